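#' Fit and evaluation statistics for DBH models
#'
#' The evaluation bundle used identically at every model stage: mean error,
#' error variance (N-1 denominator), total relative error (TRE), coefficient
#' of determination (R2), and RMSE defined as the square root of
#' (mean error)^2 + error variance — a decomposition of the mean squared
#' error into bias and dispersion, up to the N-1 convention.
#'
#' @param observed numeric vector of observed DBH (cm), length >= 2.
#' @param predicted numeric vector of predictions, same length.
#' @return object of class `fit_statistics`: list with `mean_error`,
#'   `error_variance`, `tre`, `r2`, `rmse`, `n`.
#' @export
fit_statistics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted)) {
    stop("missing values in observed or predicted", call. = FALSE)
  }
  sum_obs2 <- sum(observed^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (sum_obs2 == 0) stop("TRE undefined: observations all zero", call. = FALSE)
  if (ss_tot == 0) stop("R2 undefined: observations all equal", call. = FALSE)
  e <- observed - predicted
  me <- mean(e)
  ev <- sum((e - me)^2) / (n - 1)
  sse <- sum(e^2)
  out <- list(
    mean_error = me,
    error_variance = ev,
    tre = 100 * sse / sum_obs2,
    r2 = 1 - sse / ss_tot,
    rmse = sqrt(me^2 + ev),
    n = n
  )
  class(out) <- "fit_statistics"
  out
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf(
    "Fit statistics (n = %d)\n  mean error     %10.4f cm\n  error variance %10.4f cm^2\n  RMSE           %10.4f cm\n  R2             %10.4f\n  TRE            %10.4f\n",
    x$n, x$mean_error, x$error_variance, x$rmse, x$r2, x$tre))
  invisible(x)
}

#' Information criteria
#'
#' AIC = 2k - 2 lnL and BIC = k ln(n) - 2 lnL, with `k` counting every
#' estimated quantity: mean-function coefficients, the residual scale, each
#' random-effect covariance component, and each variance-function parameter.
#' `n` is the number of tree records, not the number of genotypes.
#'
#' @param loglik log-likelihood at the optimum.
#' @param k number of estimated parameters (>= 1).
#' @param n sample size (>= 1).
#' @return object of class `information_criteria`: list with `loglik`, `k`,
#'   `n`, `aic`, `bic`.
#' @export
information_criteria <- function(loglik, k, n) {
  if (!is.finite(loglik)) stop("loglik must be finite", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  out <- list(loglik = loglik, k = k, n = n,
              aic = 2 * k - 2 * loglik,
              bic = k * log(n) - 2 * loglik)
  class(out) <- "information_criteria"
  out
}

#' @export
print.information_criteria <- function(x, ...) {
  cat(sprintf("logLik %.4f  k = %d  n = %d  AIC %.4f  BIC %.4f\n",
              x$loglik, x$k, x$n, x$aic, x$bic))
  invisible(x)
}

#' Relative-improvement columns between two model fits
#'
#' RMSE and TRE reductions are reported as 100*(base - new)/base; the R2
#' increase as 100*(new - base)/base.
#'
#' @param base,new `fit_statistics` objects (or lists with `rmse`, `r2`,
#'   `tre`).
#' @return named numeric: `rmse_reduction_pct`, `r2_increase_pct`,
#'   `tre_reduction_pct`.
#' @export
relative_improvement <- function(base, new) {
  c(rmse_reduction_pct = 100 * (base$rmse - new$rmse) / base$rmse,
    r2_increase_pct = 100 * (new$r2 - base$r2) / base$r2,
    tre_reduction_pct = 100 * (base$tre - new$tre) / base$tre)
}
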