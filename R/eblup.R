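#' Design matrix of a genotype's random effects
#'
#' The n x q matrix of partial derivatives of the mean function with respect
#' to the random effects, evaluated at the fixed effects plus the current
#' random-effect value. For the power model with random effects on the
#' height exponents these are analytic: `df/du_b1 = f * log(lh)` and
#' `df/du_b2 = f * log(lh) * p1`; other forms fall back to central finite
#' differences.
#'
#' @param fit an `nlme_fit` (e.g. [fit_nlme()] or [dbh_reference_fit()]).
#' @param records a `tree_data` table (one genotype's calibration records).
#' @param u numeric q-vector of current random effects (default 0).
#' @return numeric matrix, `nrow(records)` x q.
#' @export
random_effect_jacobian <- function(fit, records, u = NULL) {
  records <- tree_data(as.data.frame(records))
  q <- length(fit$re_targets)
  if (is.null(u)) u <- numeric(q)
  if (any(records$lh <= 0)) stop("lh must be positive", call. = FALSE)
  phi <- shift_params(fit$fixed, fit$re_targets, u)
  mean_gradient(fit$form, phi, records$lh, records$lcd, records$p1,
                wrt = fit$re_targets)
}

#' EBLUP calibration of genotype random effects
#'
#' Predicts each genotype's random-effect vector from a small calibration
#' subsample of measured trees by the iterative empirical best linear
#' unbiased predictor: starting from u = 0, repeat (1) evaluate the
#' random-effect design matrix Z and the working residual
#' `y - f(beta, u, x) + Z u` at the current u; (2) update
#' `u <- Psi Z' (R + Z Psi Z')^{-1} * working residual`, with R diagonal
#' from the fitted variance function at the calibration trees' covariates;
#' (3) stop when the max-norm change falls below `tol`. Genotypes with no
#' calibration trees keep u = 0 (population-level prediction).
#'
#' @param fit an `nlme_fit`.
#' @param calibration a `tree_data` table of calibration trees with `dbh`
#'   present; rows are grouped by their `genotype_id`.
#' @param tol convergence tolerance on the max-norm change (default 1e-6).
#' @param max_iter iteration cap (default 50). Setting `fixed_pass` runs
#'   exactly that many update passes with no convergence check.
#' @param fixed_pass optional integer: run a fixed number of passes instead
#'   of iterating to convergence.
#' @return object of class `calibration_result`: list with `u_hat`
#'   (genotype x q matrix), `n_iter` (per genotype), `converged` (per
#'   genotype), `calibration_trees` (per-genotype row indices into
#'   `calibration`).
#' @export
eblup <- function(fit, calibration, tol = 1e-6, max_iter = 50,
                  fixed_pass = NULL) {
  calibration <- tree_data(as.data.frame(calibration))
  if (nrow(calibration) > 0 && anyNA(calibration$dbh)) {
    stop("calibration records must carry dbh", call. = FALSE)
  }
  q <- length(fit$re_targets)
  groups <- if (nrow(calibration) > 0) make_groups(calibration) else list()
  ids <- names(groups)
  u_hat <- matrix(0, length(ids), q, dimnames = list(ids, fit$re_targets))
  n_iter <- stats::setNames(integer(length(ids)), ids)
  conv <- stats::setNames(rep(TRUE, length(ids)), ids)
  psi <- fit$psi
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    recs <- calibration[idx, , drop = FALSE]
    y <- recs$dbh
    rvar <- variance_weights(fit$variance, recs[[fit$variance$covariate]])
    u <- numeric(q)
    iters <- if (is.null(fixed_pass)) max_iter else fixed_pass
    for (it in seq_len(iters)) {
      Z <- random_effect_jacobian(fit, recs, u)
      f <- predict_mean(fit$form, shift_params(fit$fixed, fit$re_targets, u),
                        recs$lh, recs$lcd, recs$p1)
      resid_work <- y - f + drop(Z %*% u)
      V <- diag(rvar, nrow = length(y)) + Z %*% psi %*% t(Z)
      Vc <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(Vc)) {
        stop("singular calibration variance matrix for genotype '",
             ids[g], "'", call. = FALSE)
      }
      u_new <- drop(psi %*% t(Z) %*%
                      backsolve(Vc, forwardsolve(t(Vc), resid_work)))
      delta <- max(abs(u_new - u))
      u <- u_new
      if (is.null(fixed_pass) && delta < tol) break
    }
    n_iter[g] <- it
    if (is.null(fixed_pass) && delta >= tol) conv[g] <- FALSE
    u_hat[g, ] <- u
  }
  out <- list(u_hat = u_hat, n_iter = n_iter, converged = conv,
              calibration_trees = groups)
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("EBLUP calibration: %d genotype(s), %d random effect(s)\n",
              nrow(x$u_hat), ncol(x$u_hat)))
  if (nrow(x$u_hat) > 0) print(round(utils::head(x$u_hat, 10), 5))
  invisible(x)
}

#' Predict DBH at the population or calibrated level
#'
#' Without a calibration result the prediction is the mean function at
#' u = 0 (population level). With one, each record uses the EBLUP u of its
#' genotype; genotypes absent from the calibration fall back to u = 0.
#'
#' @param fit an `nlme_fit`.
#' @param data a `tree_data` table with `lh`, `lcd`, `p1`.
#' @param calibration optional [eblup()] result.
#' @return numeric vector of predicted DBH (cm), one per record.
#' @export
predict_dbh <- function(fit, data, calibration = NULL) {
  data <- tree_data(as.data.frame(data))
  q <- length(fit$re_targets)
  pred <- numeric(nrow(data))
  groups <- make_groups(data)
  for (g in names(groups)) {
    idx <- groups[[g]]
    u <- numeric(q)
    if (!is.null(calibration) && g %in% rownames(calibration$u_hat)) {
      u <- calibration$u_hat[g, ]
    }
    phi <- shift_params(fit$fixed, fit$re_targets, u)
    pred[idx] <- predict_mean(fit$form, phi, data$lh[idx], data$lcd[idx],
                              data$p1[idx])
  }
  pred
}
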