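#' Calibration-subsample selection within one genotype
#'
#' Four schemes for picking the k calibration trees of a genotype by DBH:
#' the k smallest, the k largest, k random trees among the medium-sized
#' (strictly between the genotype's 20th and 80th DBH percentiles, linear
#' interpolation), or k random trees regardless of size. Ties are broken by
#' original record order; k is clipped to the group size.
#'
#' @param group one genotype's records (`tree_data`) with `dbh` present.
#' @param kind `"smallest"`, `"largest"`, `"medium"` or `"random"`.
#' @param k number of calibration trees (>= 1).
#' @param lower_pct,upper_pct percentile bounds for `"medium"` (default
#'   20 and 80).
#' @param seed RNG seed for the stochastic kinds (`NULL` = current RNG
#'   state).
#' @return integer row indices into `group`.
#' @export
select_calibration_trees <- function(group,
                                     kind = c("smallest", "largest",
                                              "medium", "random"),
                                     k, lower_pct = 20, upper_pct = 80,
                                     seed = NULL) {
  kind <- match.arg(kind)
  group <- tree_data(as.data.frame(group))
  n <- nrow(group)
  if (n == 0) stop("empty genotype group", call. = FALSE)
  if (anyNA(group$dbh)) stop("calibration selection needs dbh", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100)) {
    stop("need 0 <= lower_pct < upper_pct <= 100", call. = FALSE)
  }
  k <- min(k, n)
  if (!is.null(seed)) set.seed(seed)
  switch(kind,
    smallest = order(group$dbh, seq_len(n))[seq_len(k)],
    largest = order(-group$dbh, seq_len(n))[seq_len(k)],
    medium = {
      bounds <- stats::quantile(group$dbh, c(lower_pct, upper_pct) / 100,
                                type = 7, names = FALSE)
      eligible <- which(group$dbh > bounds[1] & group$dbh < bounds[2])
      if (length(eligible) < k) {
        warning("fewer than k trees strictly between the percentile bounds; ",
                "returning all ", length(eligible), " eligible")
        eligible
      } else {
        sort(sample(eligible, k))
      }
    },
    random = sort(sample.int(n, k)))
}

calibration_rows <- function(data, kind, k, seed = NULL, lower_pct = 20,
                             upper_pct = 80) {
  groups <- make_groups(data)
  if (!is.null(seed)) set.seed(seed)
  unlist(lapply(groups, function(idx) {
    sel <- select_calibration_trees(data[idx, , drop = FALSE], kind, k,
                                    lower_pct, upper_pct, seed = NULL)
    idx[sel]
  }), use.names = FALSE)
}

#' Evaluate calibration sampling strategies
#'
#' For each strategy kind and each k in `k_range`: select k calibration
#' trees per genotype, predict their genotype random effects by [eblup()],
#' predict DBH for the evaluation trees with the calibrated model, and
#' compute [fit_statistics()] pooled across genotypes. Stochastic kinds
#' (`"medium"`, `"random"`) are averaged over `repeats` seeded draws. The
#' default evaluation scope excludes the calibration trees themselves
#' (no leakage); `scope = "all"` evaluates over every tree.
#'
#' @param fit an `nlme_fit`.
#' @param data a `tree_data` table with `dbh` for all records.
#' @param kinds character vector of strategy kinds.
#' @param k_range integer vector of calibration sizes (default 1:10).
#' @param seed base RNG seed.
#' @param repeats number of repeats for the stochastic kinds (default 10).
#' @param scope `"holdout"` (default; evaluate non-calibration trees) or
#'   `"all"`.
#' @return data.frame with one row per (kind, k): pooled `rmse`, `r2`,
#'   `tre`, `mean_error`, `n_eval`, plus the baseline row `kind =
#'   "population", k = 0` (prediction at u = 0 over all trees).
#' @export
evaluate_strategies <- function(fit, data,
                                kinds = c("smallest", "largest", "medium",
                                          "random"),
                                k_range = 1:10, seed = 1L, repeats = 10L,
                                scope = c("holdout", "all")) {
  scope <- match.arg(scope)
  data <- tree_data(as.data.frame(data))
  if (anyNA(data$dbh)) stop("evaluation needs dbh on every record",
                            call. = FALSE)
  pop_pred <- predict_dbh(fit, data)
  pop <- fit_statistics(data$dbh, pop_pred)
  rows <- list(data.frame(kind = "population", k = 0, rmse = pop$rmse,
                          r2 = pop$r2, tre = pop$tre,
                          mean_error = pop$mean_error, n_eval = pop$n))
  stochastic <- c("medium", "random")
  for (kind in kinds) {
    for (k in k_range) {
      reps <- if (kind %in% stochastic) repeats else 1L
      acc <- matrix(NA_real_, reps, 5)
      for (r in seq_len(reps)) {
        cal_idx <- calibration_rows(data, kind, k,
                                    seed = seed + 1000L * r +
                                      k + match(kind, kinds) * 100L)
        cal <- eblup(fit, data[cal_idx, , drop = FALSE])
        eval_idx <- if (scope == "holdout")
          setdiff(seq_len(nrow(data)), cal_idx) else seq_len(nrow(data))
        if (length(eval_idx) < 2) {
          stop("fewer than 2 evaluation trees left; use scope = 'all'",
               call. = FALSE)
        }
        pred <- predict_dbh(fit, data[eval_idx, , drop = FALSE], cal)
        st <- fit_statistics(data$dbh[eval_idx], pred)
        acc[r, ] <- c(st$rmse, st$r2, st$tre, st$mean_error, st$n)
      }
      m <- colMeans(acc)
      rows[[length(rows) + 1]] <- data.frame(
        kind = kind, k = k, rmse = m[1], r2 = m[2], tre = m[3],
        mean_error = m[4], n_eval = m[5])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "scope") <- scope
  out
}

#' Leave-one-genotype-out cross-validation
#'
#' Each genotype in turn is the validation set: the NLME model is fitted on
#' the remaining genotypes, `calibration_k` random trees of the held-out
#' genotype predict its random effects by [eblup()], and the genotype's
#' remaining trees are predicted with the calibrated model. Residuals are
#' pooled across folds for the overall statistics.
#'
#' @param data a `tree_data` table with `dbh` everywhere, >= 3 genotypes.
#' @param form a [model_form()].
#' @param re_targets random-effect coefficient subset.
#' @param variance,variance_covariate passed to [fit_nlme()].
#' @param calibration_k random calibration trees per held-out genotype
#'   (default 2; 0 gives pure population-level out-of-sample prediction).
#' @param seed base seed; fold g uses `seed + g` for its calibration draw.
#' @param refit if `FALSE`, fit once on the full data and only re-estimate
#'   fixed effects and BLUPs per fold with the global variance components
#'   held fixed (fast mode for large simulations).
#' @param control passed to [fit_nlme()].
#' @return list with `pooled` ([fit_statistics()] over all held-out trees),
#'   `folds` (per-genotype data.frame), and `skipped` (genotypes whose fold
#'   fit failed).
#' @export
loocv_by_genotype <- function(data, form, re_targets,
                              variance = c("constant", "power",
                                           "exponential"),
                              variance_covariate = c("lh", "lcd"),
                              calibration_k = 2L, seed = 1L, refit = TRUE,
                              control = list()) {
  variance <- match.arg(variance)
  variance_covariate <- match.arg(variance_covariate)
  data <- tree_data(as.data.frame(data))
  groups <- make_groups(data)
  if (length(groups) < 3) stop("need at least 3 genotypes", call. = FALSE)
  global_fit <- if (!refit) {
    fit_nlme(data, form, re_targets, variance, variance_covariate,
             control = control)
  } else NULL
  obs_all <- numeric(0); pred_all <- numeric(0)
  fold_rows <- list(); skipped <- character(0)
  for (g in seq_along(groups)) {
    gid <- names(groups)[g]
    test_idx <- groups[[g]]
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    fold_fit <- tryCatch({
      if (refit) {
        fit_nlme(train, form, re_targets, variance, variance_covariate,
                 control = control)
      } else {
        # fast mode: variance components from the global fit; fold-level
        # fixed effects and BLUPs from a single penalized refit
        refit_fixed_given_variance(train, global_fit, control)
      }
    }, error = function(e) e)
    if (inherits(fold_fit, "error")) {
      skipped <- c(skipped, gid)
      next
    }
    if (calibration_k > 0) {
      set.seed(seed + g)
      sel <- select_calibration_trees(test, "random",
                                      min(calibration_k, nrow(test) - 1L))
      cal <- eblup(fold_fit, test[sel, , drop = FALSE])
      eval_idx <- setdiff(seq_len(nrow(test)), sel)
    } else {
      cal <- NULL
      eval_idx <- seq_len(nrow(test))
    }
    pred <- predict_dbh(fold_fit, test[eval_idx, , drop = FALSE], cal)
    obs <- test$dbh[eval_idx]
    obs_all <- c(obs_all, obs); pred_all <- c(pred_all, pred)
    st <- if (length(obs) >= 2) fit_statistics(obs, pred) else NULL
    fold_rows[[gid]] <- data.frame(
      genotype_id = gid, n_eval = length(obs),
      rmse = if (is.null(st)) NA_real_ else st$rmse,
      r2 = if (is.null(st)) NA_real_ else st$r2,
      tre = if (is.null(st)) NA_real_ else st$tre)
  }
  list(pooled = fit_statistics(obs_all, pred_all),
       folds = do.call(rbind, c(fold_rows, list(make.row.names = FALSE))),
       skipped = skipped)
}

# Fast-mode per-fold update: hold the global fit's Psi, sigma, gamma fixed
# and redo only the penalized nonlinear least-squares pass on the training
# fold, giving fold-level fixed effects and BLUPs.
refit_fixed_given_variance <- function(train, global_fit, control = list()) {
  ctrl <- utils::modifyList(list(pnls_iter = 50), control)
  form <- global_fit$form
  targets <- global_fit$re_targets
  q <- length(targets)
  groups <- make_groups(train)
  D <- global_fit$psi / global_fit$variance$sigma^2
  Dinv <- chol2inv(chol(D + diag(1e-12, q)))
  lam <- rel_variance(global_fit$variance$kind, global_fit$variance$gamma,
                      train[[global_fit$variance$covariate]])
  U <- matrix(0, length(groups), q,
              dimnames = list(names(groups), targets))
  pn <- pnls_step(train, groups, form, targets, global_fit$fixed, U, Dinv,
                  lam, max_iter = ctrl$pnls_iter)
  out <- global_fit
  out$fixed <- pn$beta
  out$blups <- pn$U
  out$genotypes <- names(groups)
  out
}
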