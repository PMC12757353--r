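#' Residual variance functions
#'
#' Heteroscedastic within-genotype residual variance modelled as a function
#' of a covariate x (LiDAR height or crown diameter):
#' constant `sigma^2`, power `sigma^2 * x^(2*gamma)`, or exponential
#' `sigma^2 * exp(2*gamma*x)`. With `gamma = 0` both non-constant kinds
#' reduce to the homoscedastic model.
#'
#' @param kind `"constant"`, `"power"` or `"exponential"`.
#' @param covariate `"lh"` or `"lcd"`; which tree variable drives the
#'   variance.
#' @param sigma residual scale (> 0).
#' @param gamma variance-function exponent (ignored for `"constant"`).
#' @return object of class `variance_spec`.
#' @export
variance_spec <- function(kind = c("constant", "power", "exponential"),
                          covariate = c("lh", "lcd"),
                          sigma = 1, gamma = 0) {
  kind <- match.arg(kind)
  covariate <- match.arg(covariate)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (!is.finite(gamma)) stop("gamma must be finite", call. = FALSE)
  structure(list(kind = kind, covariate = covariate, sigma = sigma,
                 gamma = if (kind == "constant") 0 else gamma),
            class = "variance_spec")
}

#' Per-observation residual variances
#'
#' @param spec a [variance_spec()].
#' @param x covariate values (must be positive under the power kind).
#' @return numeric vector of residual variances, `sigma^2 * g(x)`.
#' @export
variance_weights <- function(spec, x) {
  spec$sigma^2 * rel_variance(spec$kind, spec$gamma, x)
}

# relative variance g(x; gamma) with sigma^2 factored out
rel_variance <- function(kind, gamma, x) {
  switch(kind,
    constant = rep(1, length(x)),
    power = {
      if (any(x <= 0)) {
        stop("power variance function requires positive covariate values",
             call. = FALSE)
      }
      x^(2 * gamma)
    },
    exponential = exp(2 * gamma * x))
}

#' Enumerate candidate random-effect configurations
#'
#' All non-empty subsets of the mean function's coefficients, ordered by
#' subset size then lexicographically — the search space for
#' [search_random_effects()] (2^p - 1 configurations for p coefficients).
#'
#' @param form a [model_form()].
#' @return list of character vectors of coefficient names.
#' @export
enumerate_re_configs <- function(form) {
  coefs <- sort(form$coef)
  subsets <- list()
  for (size in seq_along(coefs)) {
    combos <- utils::combn(coefs, size, simplify = FALSE)
    subsets <- c(subsets, combos)
  }
  subsets
}

# --- internal parameterizations ------------------------------------------

# log-Cholesky: D = L L', L lower triangular, diag(L) = exp(theta[1:q]),
# strict lower triangle filled column-wise with the remaining entries.
theta_to_L <- function(theta, q) {
  L <- matrix(0, q, q)
  diag(L) <- exp(theta[seq_len(q)])
  if (q > 1) L[lower.tri(L)] <- theta[-seq_len(q)]
  L
}

psi_to_theta <- function(psi, sigma2) {
  D <- psi / sigma2
  q <- nrow(D)
  # guard: force PSD-with-margin before factorizing
  eig <- eigen(D, symmetric = TRUE)
  vals <- pmax(eig$values, 1e-10 * max(eig$values, 1e-8))
  D <- eig$vectors %*% diag(vals, q) %*% t(eig$vectors)
  L <- t(chol(D))
  c(log(diag(L)), L[lower.tri(L)])
}

n_theta <- function(q) q * (q + 1) / 2

# group bookkeeping: list of integer index vectors per genotype
make_groups <- function(data) {
  split(seq_len(nrow(data)),
        factor(data$genotype_id, levels = unique(data$genotype_id)))
}

# coefficient vector for group i: beta with targeted entries shifted by u
shift_params <- function(beta, targets, u) {
  beta[targets] <- beta[targets] + u
  beta
}

# --- penalized nonlinear least squares (inner step) ----------------------

# Minimizes sum_i |(y_i - f_i)/sqrt(lam_i)|^2 + u_i' Dinv u_i over (beta, U)
# by Gauss-Newton with arrowhead elimination of the per-group u_i blocks and
# step halving on the objective.
pnls_step <- function(data, groups, form, targets, beta, U, Dinv, lam,
                      max_iter = 50, tol = 1e-10) {
  p <- length(form$coef)
  q <- length(targets)
  sw <- 1 / sqrt(lam)
  obj_value <- function(beta, U) {
    tot <- 0
    for (i in seq_along(groups)) {
      idx <- groups[[i]]
      f <- predict_mean(form, shift_params(beta, targets, U[i, ]),
                        data$lh[idx], data$lcd[idx], data$p1[idx])
      tot <- tot + sum(((data$dbh[idx] - f) * sw[idx])^2) +
        drop(U[i, ] %*% Dinv %*% U[i, ])
    }
    tot
  }
  obj <- obj_value(beta, U)
  for (iter in seq_len(max_iter)) {
    S <- matrix(0, p, p); rhs <- numeric(p)
    Cinv_list <- vector("list", length(groups))
    b_list <- vector("list", length(groups))
    BtA_list <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      idx <- groups[[i]]
      phi <- shift_params(beta, targets, U[i, ])
      f <- predict_mean(form, phi, data$lh[idx], data$lcd[idx], data$p1[idx])
      G <- mean_gradient(form, phi, data$lh[idx], data$lcd[idx],
                         data$p1[idx])
      A <- G * sw[idx]
      B <- A[, targets, drop = FALSE]
      e <- (data$dbh[idx] - f) * sw[idx]
      C <- crossprod(B) + Dinv
      Cc <- tryCatch(chol(C), error = function(err) NULL)
      if (is.null(Cc)) Cc <- chol(C + diag(1e-8, q))
      bi <- drop(crossprod(B, e)) - drop(Dinv %*% U[i, ])
      BtA <- crossprod(B, A)
      CiB <- backsolve(Cc, forwardsolve(t(Cc), BtA))
      Cib <- backsolve(Cc, forwardsolve(t(Cc), bi))
      S <- S + crossprod(A) - crossprod(BtA, CiB)
      rhs <- rhs + drop(crossprod(A, e)) - drop(crossprod(BtA, Cib))
      Cinv_list[[i]] <- Cc; b_list[[i]] <- bi; BtA_list[[i]] <- BtA
    }
    dbeta <- tryCatch(solve(S, rhs), error = function(err)
      solve(S + diag(1e-8 * (1 + max(abs(diag(S)))), p), rhs))
    dU <- matrix(0, length(groups), q)
    for (i in seq_along(groups)) {
      ri <- b_list[[i]] - drop(BtA_list[[i]] %*% dbeta)
      dU[i, ] <- backsolve(Cinv_list[[i]],
                           forwardsolve(t(Cinv_list[[i]]), ri))
    }
    step <- 1
    repeat {
      beta_new <- beta; beta_new[] <- beta + step * dbeta
      U_new <- U + step * dU
      obj_new <- obj_value(beta_new, U_new)
      if (is.finite(obj_new) && obj_new <= obj + 1e-12) break
      step <- step / 2
      if (step < 1e-10) { obj_new <- obj; beta_new <- beta; U_new <- U; break }
    }
    improved <- obj - obj_new
    beta <- beta_new; U <- U_new; obj <- obj_new
    if (improved <= tol * (abs(obj) + 1)) break
  }
  list(beta = beta, U = U, objective = obj, n_iter = iter)
}

# --- profiled linearized likelihood (LME step) ---------------------------

# Given the working linear model w_i = X_i beta + Z_i u_i + e_i with
# Var(u) = sigma^2 D, Var(e) = sigma^2 Lam_i, return the ML log-likelihood
# profiled over beta (GLS) and sigma^2, plus the profile estimates.
lme_profile <- function(par, work, q, est_gamma, var_kind, xvar, groups) {
  theta <- par[seq_len(n_theta(q))]
  gamma <- if (est_gamma) par[n_theta(q) + 1] else 0
  L <- theta_to_L(theta, q)
  lam <- rel_variance(var_kind, gamma, xvar)
  sw <- 1 / sqrt(lam)
  p <- ncol(work$X)
  XtWX <- matrix(0, p, p); XtWw <- numeric(p); wtWw <- 0
  logdet <- sum(log(lam))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    Xs <- work$X[idx, , drop = FALSE] * sw[idx]
    Zs <- work$Z[idx, , drop = FALSE] * sw[idx]
    ws <- work$w[idx] * sw[idx]
    ZtZ <- crossprod(Zs)
    M <- diag(q) + crossprod(L, ZtZ %*% L)
    Mc <- tryCatch(chol(M), error = function(err) NULL)
    if (is.null(Mc)) return(list(ll = -Inf))
    logdet <- logdet + 2 * sum(log(diag(Mc)))
    # U' W^{-1} V = U'V - (U'Z L) M^{-1} (L'Z'V)
    XtZL <- crossprod(Xs, Zs) %*% L
    wtZL <- drop(crossprod(ws, Zs) %*% L)
    sXtZL <- backsolve(Mc, forwardsolve(t(Mc), t(XtZL)))
    swtZL <- backsolve(Mc, forwardsolve(t(Mc), wtZL))
    XtWX <- XtWX + crossprod(Xs) - XtZL %*% sXtZL
    XtWw <- XtWw + drop(crossprod(Xs, ws)) - drop(XtZL %*% swtZL)
    wtWw <- wtWw + sum(ws^2) - sum(wtZL * swtZL)
  }
  beta <- tryCatch(solve(XtWX, XtWw), error = function(err) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  rss <- wtWw - 2 * sum(beta * XtWw) + drop(beta %*% XtWX %*% beta)
  N <- length(work$w)
  if (rss <= 0) return(list(ll = -Inf))
  sigma2 <- rss / N
  ll <- -0.5 * (N * log(2 * pi * sigma2) + logdet + N)
  list(ll = ll, beta = beta, sigma2 = sigma2, L = L, gamma = gamma)
}

#' Fit the genotype nonlinear mixed-effects model
#'
#' Maximum-likelihood estimation of the single-level NLME model
#' `y_ij = f(beta + B u_i, x_ij) + e_ij`, with genotype random effects
#' `u_i ~ N(0, Psi)` on a chosen subset of mean-function coefficients,
#' unstructured `Psi`, and within-genotype residuals that are independent
#' with a constant, power, or exponential variance function.
#'
#' Estimation is an alternating Lindstrom-Bates scheme: (a) penalized
#' nonlinear least squares in (beta, u) given the variance components,
#' solved by Gauss-Newton with step halving; (b) a linear mixed-effects step
#' on the working linearized response, maximizing the likelihood profiled
#' over beta and sigma^2 with respect to the log-Cholesky factor of
#' `Psi/sigma^2` and the variance exponent gamma. Alternation stops when the
#' relative log-likelihood change falls below `tol_loglik` and the maximum
#' parameter change below `tol_param`.
#'
#' @param data a `tree_data` table with `dbh` present; every genotype should
#'   have at least 2 trees for the covariance to be identifiable.
#' @param form a [model_form()].
#' @param re_targets character vector naming the coefficients that carry
#'   genotype random effects (subset of `form$coef`).
#' @param variance `"constant"`, `"power"` or `"exponential"`.
#' @param variance_covariate `"lh"` (default) or `"lcd"`.
#' @param init optional list with elements `beta` (named), `psi`, `sigma`,
#'   `gamma` used as starting values.
#' @param control list: `max_alternations` (default 200), `tol_loglik`
#'   (1e-8, relative), `tol_param` (1e-6), `pnls_iter` (50).
#' @return object of class `nlme_fit`: `form`, `fixed` (named coefficients),
#'   `re_targets`, `psi` (q x q), `variance` ([variance_spec()]), `blups`
#'   (genotype x target matrix of predicted random effects), `loglik`, `ic`,
#'   `converged`, `n_iter`, plus the fitted values and residuals on the
#'   training data.
#' @export
fit_nlme <- function(data, form, re_targets,
                     variance = c("constant", "power", "exponential"),
                     variance_covariate = c("lh", "lcd"),
                     init = NULL, control = list()) {
  variance <- match.arg(variance)
  variance_covariate <- match.arg(variance_covariate)
  ctrl <- utils::modifyList(list(max_alternations = 200, tol_loglik = 1e-8,
                                 tol_param = 1e-6, pnls_iter = 50), control)
  data <- tree_data(as.data.frame(data))
  if (anyNA(data$dbh)) stop("all records need dbh for fitting", call. = FALSE)
  if (!all(re_targets %in% form$coef)) {
    stop("re_targets must name coefficients of the model form", call. = FALSE)
  }
  re_targets <- form$coef[form$coef %in% re_targets]  # canonical order
  q <- length(re_targets)
  groups <- make_groups(data)
  M <- length(groups)
  N <- nrow(data)
  xvar <- data[[variance_covariate]]
  if (variance == "power" && any(xvar <= 0)) {
    stop("power variance function requires positive ", variance_covariate,
         call. = FALSE)
  }
  est_gamma <- variance != "constant"

  # starting values
  if (!is.null(init$beta)) {
    beta <- check_params(form, unlist(init$beta))
  } else {
    beta <- fit_fixed_model(data, form)$params
  }
  sigma2 <- if (!is.null(init$sigma)) init$sigma^2 else
    mean((data$dbh - predict_mean(form, beta, data$lh, data$lcd,
                                  data$p1))^2)
  theta <- if (!is.null(init$psi)) psi_to_theta(init$psi, sigma2) else
    c(rep(log(0.3), q), rep(0, n_theta(q) - q))
  gamma <- if (!is.null(init$gamma)) init$gamma else
    if (est_gamma) 0.5 else 0
  U <- matrix(0, M, q, dimnames = list(names(groups), re_targets))

  npar_var <- n_theta(q) + as.integer(est_gamma)
  lower <- c(rep(-8, q), rep(-20, n_theta(q) - q),
             if (est_gamma) -3)
  upper <- c(rep(4, q), rep(20, n_theta(q) - q),
             if (est_gamma) 3)

  ll_old <- -Inf
  converged <- FALSE
  fit_ll <- NA_real_
  for (alt in seq_len(ctrl$max_alternations)) {
    # (a) PNLS in (beta, U) given variance components
    L <- theta_to_L(theta, q)
    D <- tcrossprod(L)
    Dinv <- chol2inv(chol(D + diag(1e-12, q)))
    lam <- rel_variance(variance, gamma, xvar)
    pn <- pnls_step(data, groups, form, re_targets, beta, U, Dinv, lam,
                    max_iter = ctrl$pnls_iter)
    beta_pn <- pn$beta; U <- pn$U

    # (b) LME step on the working linearized response
    Xw <- matrix(0, N, length(form$coef),
                 dimnames = list(NULL, form$coef))
    w <- numeric(N)
    for (i in seq_along(groups)) {
      idx <- groups[[i]]
      phi <- shift_params(beta_pn, re_targets, U[i, ])
      f <- predict_mean(form, phi, data$lh[idx], data$lcd[idx], data$p1[idx])
      G <- mean_gradient(form, phi, data$lh[idx], data$lcd[idx],
                         data$p1[idx])
      Xw[idx, ] <- G
      w[idx] <- data$dbh[idx] - f + drop(G %*% beta_pn) +
        drop(G[, re_targets, drop = FALSE] %*% U[i, ])
    }
    work <- list(X = Xw, Z = Xw[, re_targets, drop = FALSE], w = w)
    par0 <- c(theta, if (est_gamma) gamma)
    opt <- stats::optim(par0, function(par) {
      -lme_profile(par, work, q, est_gamma, variance, xvar, groups)$ll
    }, method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = 100, factr = 1e4))
    prof <- lme_profile(opt$par, work, q, est_gamma, variance, xvar, groups)
    theta_new <- opt$par[seq_len(n_theta(q))]
    gamma_new <- if (est_gamma) opt$par[n_theta(q) + 1] else 0
    beta_new <- prof$beta
    names(beta_new) <- form$coef
    sigma2 <- prof$sigma2
    fit_ll <- prof$ll

    dpar <- max(abs(c(theta_new - theta, gamma_new - gamma,
                      beta_new - beta_pn)))
    dll <- abs(fit_ll - ll_old) / (abs(fit_ll) + 1)
    theta <- theta_new; gamma <- gamma_new; beta <- beta_new
    ll_old <- fit_ll
    if (alt > 1 && dll < ctrl$tol_loglik && dpar < ctrl$tol_param) {
      converged <- TRUE
      break
    }
  }
  if (!converged && ctrl$max_alternations > 2) {
    warning("fit_nlme: alternation limit reached without convergence")
  }

  # final PNLS pass so the reported u are the posterior modes at the
  # converged variance components
  L <- theta_to_L(theta, q)
  D <- tcrossprod(L)
  Dinv <- chol2inv(chol(D + diag(1e-12, q)))
  lam <- rel_variance(variance, gamma, xvar)
  pn <- pnls_step(data, groups, form, re_targets, beta, U, Dinv, lam,
                  max_iter = ctrl$pnls_iter)
  beta <- pn$beta; U <- pn$U

  psi <- sigma2 * D
  psi <- (psi + t(psi)) / 2
  dimnames(psi) <- list(re_targets, re_targets)
  sigma <- sqrt(sigma2)
  boundary <- any(diag(psi) < 1e-10 * sigma2)
  if (boundary) {
    warning("fit_nlme: a random-effect variance collapsed to the boundary")
  }
  vspec <- variance_spec(variance, variance_covariate, sigma = sigma,
                         gamma = gamma)
  fitted <- numeric(N)
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    phi <- shift_params(beta, re_targets, U[i, ])
    fitted[idx] <- predict_mean(form, phi, data$lh[idx], data$lcd[idx],
                                data$p1[idx])
  }
  k <- length(form$coef) + 1L + n_theta(q) + as.integer(est_gamma)
  out <- list(
    form = form, fixed = beta, re_targets = re_targets, psi = psi,
    variance = vspec,
    blups = U,
    loglik = fit_ll,
    ic = information_criteria(fit_ll, k = k, n = N),
    converged = converged, n_iter = alt, boundary = boundary,
    fitted = fitted, residuals = data$dbh - fitted, observed = data$dbh,
    stats = fit_statistics(data$dbh, fitted),
    genotypes = names(groups)
  )
  class(out) <- "nlme_fit"
  out
}

#' @export
print.nlme_fit <- function(x, ...) {
  cat(sprintf("Genotype NLME %s model (dummy: %s)\n", x$form$family,
              x$form$dummy_slot))
  cat("Fixed effects:\n"); print(round(x$fixed, 4))
  cat(sprintf("Random effects on: %s\n",
              paste(x$re_targets, collapse = ", ")))
  cat("Psi:\n"); print(signif(x$psi, 4))
  cat(sprintf("Residual: %s variance on %s, sigma = %.4f, gamma = %.4f\n",
              x$variance$kind, x$variance$covariate, x$variance$sigma,
              x$variance$gamma))
  if (!is.na(x$loglik)) print(x$ic)
  invisible(x)
}

#' Search over random-effect configurations
#'
#' Fits the NLME model for every non-empty subset of the form's coefficients
#' (skipping configurations whose fit fails, with the reason recorded) and
#' ranks the survivors by AIC, then BIC, then subset size.
#'
#' @inheritParams fit_nlme
#' @param configs optional list of target subsets; defaults to
#'   [enumerate_re_configs()].
#' @return list with `table` (one row per attempted configuration), `fits`
#'   (named list of successful `nlme_fit`s) and `best` (the winner).
#' @export
search_random_effects <- function(data, form,
                                  variance = c("constant", "power",
                                               "exponential"),
                                  variance_covariate = c("lh", "lcd"),
                                  configs = NULL, control = list()) {
  variance <- match.arg(variance)
  variance_covariate <- match.arg(variance_covariate)
  if (is.null(configs)) configs <- enumerate_re_configs(form)
  labels <- vapply(configs, paste, character(1), collapse = "+")
  fits <- list(); rows <- list()
  for (j in seq_along(configs)) {
    res <- tryCatch(
      fit_nlme(data, form, configs[[j]], variance, variance_covariate,
               control = control),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[j]] <- data.frame(config = labels[j], q = length(configs[[j]]),
                              k = NA, loglik = NA, aic = NA, bic = NA,
                              converged = FALSE,
                              note = conditionMessage(res))
    } else {
      fits[[labels[j]]] <- res
      rows[[j]] <- data.frame(config = labels[j], q = length(configs[[j]]),
                              k = res$ic$k, loglik = res$loglik,
                              aic = res$ic$aic, bic = res$ic$bic,
                              converged = res$converged, note = "")
    }
  }
  tab <- do.call(rbind, rows)
  if (length(fits) == 0) stop("no random-effect configuration converged",
                              call. = FALSE)
  ok <- !is.na(tab$aic)
  ord <- order(tab$aic[ok], tab$bic[ok], tab$q[ok])
  ranked <- tab[ok, ][ord, ]
  list(table = tab, ranked = ranked, fits = fits,
       best = fits[[ranked$config[1]]])
}

#' Likelihood ratio test between nested fits
#'
#' @param nested,full fitted models (objects with `$loglik` and `$ic$k`);
#'   `nested` must have fewer parameters.
#' @return list with `statistic` (2 * loglik difference), `df` and
#'   `p_value` from the chi-square upper tail.
#' @export
likelihood_ratio_test <- function(nested, full) {
  ll_n <- if (!is.null(nested$loglik)) nested$loglik else nested$ic$loglik
  ll_f <- if (!is.null(full$loglik)) full$loglik else full$ic$loglik
  k_n <- nested$ic$k; k_f <- full$ic$k
  if (k_n >= k_f) stop("'nested' must have fewer parameters", call. = FALSE)
  stat <- 2 * (ll_f - ll_n)
  if (stat < -1e-6) {
    stop("negative LRT statistic: fits are not nested or not converged",
         call. = FALSE)
  }
  stat <- max(stat, 0)
  df <- k_f - k_n
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Reference genotype-calibrated DBH model for Catalpa bungei plantations
#'
#' The package's shipped reference model: a power mean function in LiDAR
#' height and crown diameter with a planting-density shift on the height
#' exponent, genotype random effects on the two height-exponent
#' coefficients, and a power-of-height residual variance function. Its
#' coefficients are the estimates from the Catalpa bungei clonal trial the
#' package's defaults emulate; it can be used for prediction and EBLUP
#' calibration without refitting.
#'
#' @return an `nlme_fit` object with empty BLUPs (all genotypes start at the
#'   population level) and no training-data statistics.
#' @export
dbh_reference_fit <- function() {
  form <- model_form("power", "on_b")
  psi <- matrix(c(7.763e-3, -4.857e-3, -4.857e-3, 5.401e-3), 2, 2,
                dimnames = list(c("b1", "b2"), c("b1", "b2")))
  out <- list(
    form = form,
    fixed = c(a1 = 0.8403, b1 = 1.1829, b2 = -0.1427, c1 = 0.2726),
    re_targets = c("b1", "b2"),
    psi = psi,
    variance = variance_spec("power", "lh", sigma = 0.3482, gamma = 0.8415),
    blups = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("b1", "b2"))),
    loglik = NA_real_, ic = NULL, converged = TRUE, n_iter = 0L,
    boundary = FALSE, genotypes = character(0)
  )
  class(out) <- "nlme_fit"
  out
}
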