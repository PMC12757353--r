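#' Per-tree data tables
#'
#' A tree table is the package's atomic data structure: one row per tree with
#' the genotype label, a planting-density indicator, the field-measured stem
#' diameter at breast height (DBH, cm), optional field height and crown
#' diameter (m), and the LiDAR-derived height and crown diameter (m) that
#' serve as model predictors.
#'
#' @section Canonical columns:
#' \describe{
#'   \item{genotype_id}{character; the clone / genotype label (grouping factor).}
#'   \item{p1}{integer 0/1; 1 = high-density planting.}
#'   \item{dbh}{numeric, cm, > 0; may be `NA` for pure prediction rows.}
#'   \item{h}{numeric, m, > 0; field-measured height, optional.}
#'   \item{cd}{numeric, m, > 0; field-measured crown diameter, optional.}
#'   \item{lh}{numeric, m, > 0; LiDAR-derived height, required.}
#'   \item{lcd}{numeric, m, >= 0; LiDAR-derived crown diameter, required.}
#' }
#'
#' @name tree_data
NULL

TREE_COLUMNS <- c("genotype_id", "p1", "dbh", "h", "cd", "lh", "lcd")
TREE_NUMERIC <- c("p1", "dbh", "h", "cd", "lh", "lcd")

#' Construct and validate a tree table
#'
#' @param df data.frame with (at least) the canonical columns
#'   `genotype_id`, `p1`, `lh`, `lcd`; `dbh`, `h`, `cd` are optional and
#'   filled with `NA` when missing.
#' @return a `tree_data` data.frame with columns in canonical order and
#'   `genotype_id` as character.
#' @export
tree_data <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("genotype_id", "p1", "lh", "lcd")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(TREE_COLUMNS, names(df))) df[[col]] <- NA_real_
  df <- df[TREE_COLUMNS]
  df$genotype_id <- as.character(df$genotype_id)
  for (col in TREE_NUMERIC) df[[col]] <- as.numeric(df[[col]])
  validate_tree_data(df)
  class(df) <- c("tree_data", "data.frame")
  df
}

validate_tree_data <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  bad_p1 <- which(!(df$p1 %in% c(0, 1)))
  if (length(bad_p1) > 0) {
    stop("p1 must be 0 or 1; offending row(s): ",
         paste(utils::head(bad_p1, 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$lh) || any(!is.finite(df$lh)) || any(df$lh < 0)) {
    stop("lh must be present, finite and non-negative", call. = FALSE)
  }
  if (anyNA(df$lcd) || any(!is.finite(df$lcd)) || any(df$lcd < 0)) {
    stop("lcd must be present, finite and non-negative", call. = FALSE)
  }
  has_dbh <- !is.na(df$dbh)
  if (any(df$dbh[has_dbh] <= 0)) {
    stop("dbh, when present, must be positive", call. = FALSE)
  }
  invisible(df)
}

#' Genotype grouping of a tree table
#'
#' @param data a `tree_data` table.
#' @return named list mapping each genotype id to the integer row positions
#'   of its trees, in first-appearance order.
#' @export
genotype_groups <- function(data) {
  split(seq_len(nrow(data)), factor(data$genotype_id,
                                    levels = unique(data$genotype_id)))
}

#' Read a per-tree CSV table
#'
#' Reads a comma-separated table with a header row. Arbitrary source headers
#' are supported through `column_map`; empty cells are missing values.
#'
#' @param source path to a CSV file (or a connection).
#' @param column_map optional named character vector mapping canonical names
#'   to source header names, e.g. `c(lh = "Height_L")`.
#' @return a `tree_data` table preserving input row order.
#' @export
read_tree_table <- function(source, column_map = NULL) {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("column_map names absent source column '", src, "'",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  required <- c("genotype_id", "p1", "lh", "lcd")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("input lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(TREE_COLUMNS, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[TREE_COLUMNS]
  for (col in TREE_NUMERIC) {
    txt <- raw[[col]]
    txt[txt == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(num))
    if (length(bad) > 0) {
      stop("unparseable numeric value in column '", col, "', row ", bad[1],
           call. = FALSE)
    }
    raw[[col]] <- num
  }
  tree_data(raw)
}

#' Write a per-tree CSV table
#'
#' Writes the canonical header `genotype_id,p1,dbh,h,cd,lh,lcd`; absent
#' values become empty cells; numbers are rendered at full precision so that
#' `read_tree_table(write_tree_table(x))` reproduces `x`.
#'
#' @param data a `tree_data` table.
#' @param sink output path (or connection).
#' @export
write_tree_table <- function(data, sink) {
  data <- tree_data(as.data.frame(data))
  out <- data
  for (col in TREE_NUMERIC) {
    out[[col]] <- ifelse(is.na(data[[col]]), "",
                         format(data[[col]], digits = 17, trim = TRUE,
                                scientific = FALSE))
  }
  utils::write.csv(as.data.frame(out), sink, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(NULL)
}

#' Apply the study's sample-filtering rules
#'
#' Two-stage filter: (i) remove trees whose LiDAR height and field height are
#' both below `height_floor` (breast height, 1.3 m, below which DBH is
#' undefined); (ii) remove every genotype whose remaining tree count is below
#' `min_trees`. The height rule runs first so the count threshold applies to
#' surviving trees.
#'
#' @param data a `tree_data` table.
#' @param min_trees minimum trees per genotype retained (default 30).
#' @param height_floor height threshold in metres (default 1.3).
#' @param height_rule `"and"` (default) removes a tree only when *both* lh
#'   and h are below the floor; `"or"` removes it when either is.
#' @return the filtered table, with a `filter_report` attribute listing the
#'   number of trees removed by the height rule, the number of trees removed
#'   with under-sampled genotypes, and the genotypes dropped.
#' @export
filter_dataset <- function(data, min_trees = 30, height_floor = 1.3,
                           height_rule = c("and", "or")) {
  height_rule <- match.arg(height_rule)
  data <- tree_data(as.data.frame(data))
  if (height_floor > 0 && anyNA(data$h) && nrow(data) > 0) {
    stop("height filtering requires h on every record; ",
         "set height_floor = 0 for LiDAR-only tables", call. = FALSE)
  }
  low_lh <- data$lh < height_floor
  low_h <- if (nrow(data) > 0) data$h < height_floor else logical(0)
  drop_height <- if (height_rule == "and") low_lh & low_h else low_lh | low_h
  drop_height[is.na(drop_height)] <- FALSE
  kept <- data[!drop_height, , drop = FALSE]

  counts <- table(kept$genotype_id)
  small <- names(counts)[counts < min_trees]
  drop_geno <- kept$genotype_id %in% small
  out <- kept[!drop_geno, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tree_data", "data.frame")
  attr(out, "filter_report") <- list(
    n_input = nrow(data),
    n_removed_height = sum(drop_height),
    n_removed_genotype = sum(drop_geno),
    genotypes_dropped = small,
    n_retained = nrow(out)
  )
  out
}

#' Descriptive summary of tree variables
#'
#' Per-variable mean, standard deviation (denominator N-1), maximum and
#' minimum over present values, plus the linear-fit R-squared of the standard
#' LiDAR/field variable pairs (lh~h, lcd~cd, dbh~h).
#'
#' @param data a non-empty `tree_data` table.
#' @return list with elements `variables` (data.frame, one row per variable)
#'   and `pairwise_r2` (named numeric: `lh_h`, `lcd_cd`, `dbh_h`; `NA` where
#'   a member variable is absent).
#' @export
summarize_trees <- function(data) {
  data <- tree_data(as.data.frame(data))
  if (nrow(data) == 0) stop("empty tree table", call. = FALSE)
  vars <- c("dbh", "h", "cd", "lh", "lcd")
  rows <- list()
  for (v in vars) {
    x <- data[[v]][!is.na(data[[v]])]
    if (length(x) == 0) {
      warning("variable '", v, "' entirely absent; omitted from summary")
      next
    }
    rows[[v]] <- data.frame(
      variable = v, n = length(x), mean = mean(x),
      sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
      max = max(x), min = min(x)
    )
  }
  pair_r2 <- function(y, x) {
    ok <- !is.na(y) & !is.na(x)
    if (sum(ok) < 3 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(y[ok], x[ok])^2  # simple linear-fit R-squared
  }
  list(
    variables = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    pairwise_r2 = c(lh_h = pair_r2(data$lh, data$h),
                    lcd_cd = pair_r2(data$lcd, data$cd),
                    dbh_h = pair_r2(data$dbh, data$h))
  )
}
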