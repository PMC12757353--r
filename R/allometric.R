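#' Allometric mean functions
#'
#' Four candidate base forms relating DBH (cm) to LiDAR height `lh` (m) and
#' LiDAR crown diameter `lcd` (m):
#' \describe{
#'   \item{logistic}{`a1 / (1 + b1 exp(-(c1*lh + d1*lcd)))`}
#'   \item{exponential}{`a1 exp(-b1*lh - c1*lcd)` (printed decaying form; its
#'     coefficients may fit negative to describe growth)}
#'   \item{power}{`a1 * lh^b1 * lcd^c1`}
#'   \item{richards}{`a1 * (1 - exp(-b1*lh - c1*lcd))` (no shape exponent)}
#' }
#' Only the power family carries planting-density dummy extensions, one
#' coefficient shifted at a time: `on_a` gives `(a1 + a2*p1)`, `on_b` gives
#' exponent `(b1 + b2*p1)` on `lh`, `on_c` gives exponent `(c1 + c2*p1)` on
#' `lcd`.
#'
#' @param family one of `"logistic"`, `"exponential"`, `"power"`,
#'   `"richards"`.
#' @param dummy_slot `"none"` (default) or, for the power family only,
#'   `"on_a"`, `"on_b"`, `"on_c"`.
#' @return object of class `model_form` with the ordered coefficient names.
#' @export
model_form <- function(family = c("power", "logistic", "exponential",
                                  "richards"),
                       dummy_slot = c("none", "on_a", "on_b", "on_c")) {
  family <- match.arg(family)
  dummy_slot <- match.arg(dummy_slot)
  if (dummy_slot != "none" && family != "power") {
    stop("dummy extensions are defined for the power family only",
         call. = FALSE)
  }
  coefs <- switch(family,
    logistic = c("a1", "b1", "c1", "d1"),
    exponential = c("a1", "b1", "c1"),
    power = switch(dummy_slot,
      none = c("a1", "b1", "c1"),
      on_a = c("a1", "a2", "b1", "c1"),
      on_b = c("a1", "b1", "b2", "c1"),
      on_c = c("a1", "b1", "c1", "c2")),
    richards = c("a1", "b1", "c1"))
  structure(list(family = family, dummy_slot = dummy_slot, coef = coefs),
            class = "model_form")
}

#' @export
print.model_form <- function(x, ...) {
  cat(sprintf("model_form: %s (dummy: %s); coefficients: %s\n",
              x$family, x$dummy_slot, paste(x$coef, collapse = ", ")))
  invisible(x)
}

check_params <- function(form, params) {
  params <- unlist(params)
  missing <- setdiff(form$coef, names(params))
  if (length(missing) > 0) {
    stop("params incomplete for ", form$family, " form; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params[form$coef]
}

#' Evaluate an allometric mean function
#'
#' Deterministic mean DBH at given covariates. For the power family a zero
#' `lcd` with positive exponent yields 0, and `0^0` is 1.
#'
#' @param form a [model_form()].
#' @param params named numeric vector (or list) with the form's coefficients.
#' @param lh,lcd,p1 numeric vectors (recycled): LiDAR height (> 0), LiDAR
#'   crown diameter (>= 0), density indicator (0/1).
#' @return numeric vector of mean DBH (cm).
#' @export
predict_mean <- function(form, params, lh, lcd, p1 = 0) {
  params <- check_params(form, params)
  if (any(lh <= 0)) stop("lh must be positive", call. = FALSE)
  if (any(lcd < 0)) stop("lcd must be non-negative", call. = FALSE)
  n <- max(length(lh), length(lcd), length(p1))
  lh <- rep_len(lh, n); lcd <- rep_len(lcd, n); p1 <- rep_len(p1, n)
  p <- as.list(params)
  switch(form$family,
    logistic = p$a1 / (1 + p$b1 * exp(-(p$c1 * lh + p$d1 * lcd))),
    exponential = p$a1 * exp(-p$b1 * lh - p$c1 * lcd),
    richards = p$a1 * (1 - exp(-p$b1 * lh - p$c1 * lcd)),
    power = {
      a <- p$a1 + if (form$dummy_slot == "on_a") p$a2 * p1 else 0
      b <- p$b1 + if (form$dummy_slot == "on_b") p$b2 * p1 else 0
      c <- p$c1 + if (form$dummy_slot == "on_c") p$c2 * p1 else 0
      a * lh^b * lcd^c
    })
}

# Gradient of the mean function with respect to a subset of coefficients.
# Analytic for the power family (the only family carrying random effects in
# practice); central finite differences otherwise, step 1e-6 * (1 + |value|).
mean_gradient <- function(form, params, lh, lcd, p1 = 0,
                          wrt = form$coef) {
  params <- check_params(form, params)
  n <- max(length(lh), length(lcd), length(p1))
  lh <- rep_len(lh, n); lcd <- rep_len(lcd, n); p1 <- rep_len(p1, n)
  grad <- matrix(0, n, length(wrt), dimnames = list(NULL, wrt))
  if (form$family == "power") {
    f <- predict_mean(form, params, lh, lcd, p1)
    p <- as.list(params)
    a <- p$a1 + if (form$dummy_slot == "on_a") p$a2 * p1 else 0
    loglh <- log(lh)
    # 0 * log(0) treated as 0 so that lcd = 0 rows stay finite
    loglcd <- ifelse(lcd > 0, log(lcd), 0)
    fl <- ifelse(f == 0, 0, f)
    for (w in wrt) {
      grad[, w] <- switch(w,
        a1 = ifelse(a == 0, lh^(p$b1 + if (form$dummy_slot == "on_b")
                                 p$b2 * p1 else 0) *
                      lcd^(p$c1 + if (form$dummy_slot == "on_c")
                             p$c2 * p1 else 0),
                    f / a),
        a2 = p1 * ifelse(a == 0, f, f / a),
        b1 = fl * loglh,
        b2 = fl * loglh * p1,
        c1 = fl * loglcd,
        c2 = fl * loglcd * p1,
        stop("unknown coefficient ", w))
    }
    return(grad)
  }
  for (j in seq_along(wrt)) {
    h <- 1e-6 * (1 + abs(params[wrt[j]]))
    up <- params; up[wrt[j]] <- up[wrt[j]] + h
    dn <- params; dn[wrt[j]] <- dn[wrt[j]] - h
    grad[, j] <- (predict_mean(form, up, lh, lcd, p1) -
                    predict_mean(form, dn, lh, lcd, p1)) / (2 * h)
  }
  grad
}

# Deterministic, data-driven starting values (log-linear OLS for the
# power/exponential families; scale-based heuristics for the S-shaped ones).
default_start <- function(form, data) {
  dbh <- data$dbh; lh <- data$lh
  lcd <- pmax(data$lcd, 0.05)  # clip to the observed minimum, avoids log(0)
  if (form$family == "power") {
    fit <- stats::lm(log(dbh) ~ log(lh) + log(lcd))
    st <- c(a1 = unname(exp(stats::coef(fit)[1])),
            b1 = unname(stats::coef(fit)[2]),
            c1 = unname(stats::coef(fit)[3]))
    extra <- setdiff(form$coef, names(st))
    if (length(extra) > 0) st[extra] <- 0
    return(st[form$coef])
  }
  if (form$family == "exponential") {
    fit <- stats::lm(log(dbh) ~ lh + lcd)
    return(c(a1 = unname(exp(stats::coef(fit)[1])),
             b1 = unname(-stats::coef(fit)[2]),
             c1 = unname(-stats::coef(fit)[3])))
  }
  a1 <- max(dbh) * 1.05
  if (form$family == "logistic") {
    return(c(a1 = a1, b1 = 1, c1 = 0.5, d1 = 0.5))
  }
  c(a1 = a1, b1 = 0.5, c1 = 0.5)  # richards
}

#' Fit a fixed-effects allometric model by nonlinear least squares
#'
#' Levenberg-Marquardt least squares with deterministic data-driven starting
#' values; up to 5 seeded jittered restarts on failure. The log-likelihood is
#' the i.i.d. Gaussian likelihood at the ML residual variance (RSS/n); `k`
#' counts the mean coefficients plus the residual scale.
#'
#' @param data a `tree_data` table with `dbh`, `lh`, `lcd` present.
#' @param form a [model_form()].
#' @param init optional named starting values.
#' @param restart_seed seed for the jittered restarts (default 1).
#' @return object of class `fixed_fit`: list with `form`, `params`, `fitted`,
#'   `residuals`, `stats` ([fit_statistics()]), `ic`
#'   ([information_criteria()]), `converged`, `n_iter`.
#' @export
fit_fixed_model <- function(data, form, init = NULL, restart_seed = 1L) {
  data <- tree_data(as.data.frame(data))
  if (anyNA(data$dbh)) stop("all records need dbh for fitting", call. = FALSE)
  p <- length(form$coef)
  if (nrow(data) < p + 2) stop("too few records to fit", call. = FALSE)
  if (stats::var(data$lh) == 0) {
    stop("degenerate design: lh is constant", call. = FALSE)
  }
  start <- if (is.null(init)) default_start(form, data) else
    check_params(form, unlist(init))

  df <- data.frame(dbh = data$dbh, lh = data$lh, lcd = data$lcd, p1 = data$p1)
  fml <- switch(form$family,
    logistic = dbh ~ a1 / (1 + b1 * exp(-(c1 * lh + d1 * lcd))),
    exponential = dbh ~ a1 * exp(-b1 * lh - c1 * lcd),
    richards = dbh ~ a1 * (1 - exp(-b1 * lh - c1 * lcd)),
    power = switch(form$dummy_slot,
      none = dbh ~ a1 * lh^b1 * lcd^c1,
      on_a = dbh ~ (a1 + a2 * p1) * lh^b1 * lcd^c1,
      on_b = dbh ~ a1 * lh^(b1 + b2 * p1) * lcd^c1,
      on_c = dbh ~ a1 * lh^b1 * lcd^(c1 + c2 * p1)))

  fit <- NULL
  tries <- 0L
  st <- start
  repeat {
    tries <- tries + 1L
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = df, start = as.list(st),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
    if (tries > 5L) {
      stop("nonlinear least squares failed after restarts: ",
           conditionMessage(fit), call. = FALSE)
    }
    set.seed(restart_seed + tries)
    st <- start * (1 + stats::rnorm(length(start), 0, 0.2)) +
      stats::rnorm(length(start), 0, 0.01)
  }

  params <- stats::coef(fit)[form$coef]
  fitted <- as.numeric(stats::fitted(fit))
  res <- df$dbh - fitted
  n <- nrow(df)
  # variance floor guards the degenerate zero-residual (exact-fit) case
  sigma2_ml <- max(sum(res^2) / n, 1e-12)
  loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  out <- list(
    form = form,
    params = params,
    fitted = fitted,
    residuals = res,
    observed = df$dbh,
    stats = fit_statistics(df$dbh, fitted),
    ic = information_criteria(loglik, k = p + 1L, n = n),
    converged = fit$convInfo$isConv %||% TRUE,
    n_iter = fit$convInfo$finIter %||% tries
  )
  class(out) <- "fixed_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fixed_fit <- function(x, ...) {
  cat(sprintf("Fixed-effects %s model (dummy: %s)\n", x$form$family,
              x$form$dummy_slot))
  print(round(x$params, 4))
  print(x$stats)
  print(x$ic)
  invisible(x)
}

#' Rank fitted models and report relative improvements
#'
#' @param fits named list of `fixed_fit` (or `nlme_fit`) objects fitted to
#'   the same data.
#' @param baseline name or index of the baseline fit for the
#'   relative-change columns (default: first).
#' @return data.frame ranked by AIC with columns model, k, RMSE, R2, TRE,
#'   AIC, BIC and relative-change columns versus the baseline.
#' @export
compare_models <- function(fits, baseline = 1L) {
  if (length(fits) < 2) stop("need at least 2 fits", call. = FALSE)
  ns <- vapply(fits, function(f) f$ic$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("fits are not on the same data (n differs)", call. = FALSE)
  }
  obs <- lapply(fits, `[[`, "observed")
  if (!all(vapply(obs[-1], identical, logical(1), obs[[1]]))) {
    stop("fits are not on the same data (observed values differ)",
         call. = FALSE)
  }
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  base <- fits[[baseline]]
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    imp <- relative_improvement(base$stats, f$stats)
    data.frame(model = nm, k = f$ic$k, rmse = f$stats$rmse, r2 = f$stats$r2,
               tre = f$stats$tre, aic = f$ic$aic, bic = f$ic$bic,
               rmse_reduction_pct = unname(imp[1]),
               r2_increase_pct = unname(imp[2]),
               tre_reduction_pct = unname(imp[3]))
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$aic), , drop = FALSE]
}
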