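ref_records <- function(lh, lcd = 1, p1 = 1, dbh = NA_real_,
                        id = "G1") {
  tree_data(data.frame(genotype_id = id, p1 = p1, dbh = dbh, h = NA,
                       cd = NA, lh = lh, lcd = lcd))
}

shift_by <- function(beta, targets, u) {
  beta[targets] <- beta[targets] + u
  beta
}

test_that("the random-effect design matrix has its analytic structure", {
  fit <- dbh_reference_fit()
  # log(lh) = 0 zeroes the whole row
  Z <- random_effect_jacobian(fit, ref_records(lh = 1))
  expect_equal(unname(Z), matrix(0, 1, 2))
  # the density-gated column vanishes for low-density trees
  Z0 <- random_effect_jacobian(fit, ref_records(lh = 2, p1 = 0))
  expect_equal(unname(Z0[1, 2]), 0)
  expect_gt(abs(Z0[1, 1]), 0)
  # analytic row f * ln(2) * (1, 1) at u = 0, lh = 2, lcd = 1, p1 = 1
  Z1 <- random_effect_jacobian(fit, ref_records(lh = 2, p1 = 1))
  f <- predict_mean(fit$form, fit$fixed, 2, 1, 1)
  expect_equal(unname(Z1[1, ]), rep(f * log(2), 2), tolerance = 1e-10)
  expect_equal(f, 1.728088, tolerance = 1e-6)
})

test_that("analytic jacobians agree with central finite differences", {
  fit <- dbh_reference_fit()
  recs <- ref_records(lh = c(2, 3.5, 6), lcd = c(0.8, 1.4, 2),
                      p1 = c(1, 0, 1))
  u <- c(0.05, -0.03)
  Z <- random_effect_jacobian(fit, recs, u)
  h <- 1e-6
  for (k in 1:2) {
    up <- u; up[k] <- up[k] + h
    dn <- u; dn[k] <- dn[k] - h
    fd <- (predict_mean(fit$form, shift_by(fit$fixed, fit$re_targets, up),
                        recs$lh, recs$lcd, recs$p1) -
             predict_mean(fit$form, shift_by(fit$fixed, fit$re_targets, dn),
                          recs$lh, recs$lcd, recs$p1)) / (2 * h)
    expect_equal(unname(Z[, k]), fd, tolerance = 1e-5)
  }
})

test_that("EBLUP handles the degenerate limits", {
  fit <- dbh_reference_fit()
  # empty calibration: every genotype stays at the population level
  cal <- eblup(fit, ref_records(lh = 2)[0, ])
  expect_equal(nrow(cal$u_hat), 0L)
  d <- ref_records(lh = c(2, 3), dbh = c(3, 4))
  expect_equal(predict_dbh(fit, d, cal), predict_dbh(fit, d))
  # Psi = 0 shrinks every prediction to zero regardless of data
  fit0 <- fit
  fit0$psi <- matrix(0, 2, 2, dimnames = dimnames(fit$psi))
  cal0 <- eblup(fit0, d)
  expect_equal(unname(cal0$u_hat), matrix(0, 1, 2))
})

test_that("iterated EBLUP equals the penalized posterior-mode oracle", {
  fit <- dbh_reference_fit()
  # q = 1 toy: single random effect on the height exponent, one tree
  fit1 <- fit
  fit1$re_targets <- "b1"
  fit1$psi <- matrix(4e-3, 1, 1, dimnames = list("b1", "b1"))
  one <- ref_records(lh = 3, lcd = 1.2, p1 = 0, dbh = 4.2)
  cal1 <- eblup(fit1, one, tol = 1e-10)
  pen_obj1 <- function(u) {
    f <- predict_mean(fit1$form,
                      shift_by(fit1$fixed, "b1", u), 3, 1.2, 0)
    rvar <- variance_weights(fit1$variance, 3)
    (4.2 - f)^2 / rvar + u^2 / fit1$psi[1, 1]
  }
  u_opt <- stats::optimize(pen_obj1, c(-1, 1), tol = 1e-12)$minimum
  expect_equal(unname(cal1$u_hat[1, 1]), u_opt, tolerance = 1e-4)

  # q = 2 with up to 3 calibration trees against a generic optimizer
  set.seed(61)
  for (ntree in 1:3) {
    recs <- ref_records(lh = runif(ntree, 2, 7), lcd = runif(ntree, 0.5, 3),
                        p1 = 1, dbh = runif(ntree, 2, 8))
    cal <- eblup(fit, recs, tol = 1e-12, max_iter = 200)
    rvar <- variance_weights(fit$variance, recs$lh)
    psi_inv <- solve(fit$psi)
    pen_obj <- function(u) {
      f <- predict_mean(fit$form,
                        shift_by(fit$fixed, fit$re_targets, u),
                        recs$lh, recs$lcd, recs$p1)
      sum((recs$dbh - f)^2 / rvar) + drop(u %*% psi_inv %*% u)
    }
    opt <- stats::optim(c(0, 0), pen_obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    expect_lt(max(abs(cal$u_hat[1, ] - opt$par)), 1e-4)
  }
})

test_that("inflating the residual variance shrinks the predicted effects", {
  fit <- dbh_reference_fit()
  recs <- ref_records(lh = c(2.5, 4, 5.5), lcd = c(1, 1.5, 2), p1 = 1,
                      dbh = c(4, 6.5, 9))
  norms <- sapply(c(1, 2, 5, 10, 100), function(scale) {
    f <- fit
    f$variance <- variance_spec("power", "lh",
                                sigma = fit$variance$sigma * sqrt(scale),
                                gamma = fit$variance$gamma)
    sqrt(sum(eblup(f, recs)$u_hat^2))
  })
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("calibration from model-simulated trees improves prediction", {
  set.seed(77)
  fit <- dbh_reference_fit()
  wins <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    u <- drop(t(chol(fit$psi)) %*% rnorm(2))
    lh <- runif(12, 2, 8); lcd <- 0.7 + 0.3 * lh + rnorm(12, 0, 0.3)
    phi <- shift_by(fit$fixed, fit$re_targets, u)
    mu <- predict_mean(fit$form, phi, lh, pmax(lcd, 0.05), 1)
    dbh <- mu + rnorm(12, 0, sqrt(variance_weights(fit$variance, lh)))
    d <- ref_records(lh = lh, lcd = pmax(lcd, 0.05), p1 = 1,
                     dbh = pmax(dbh, 0.11))
    cal <- eblup(fit, d[1:4, ])
    test <- d[5:12, ]
    rmse_cal <- sqrt(mean((test$dbh - predict_dbh(fit, test, cal))^2))
    rmse_pop <- sqrt(mean((test$dbh - predict_dbh(fit, test))^2))
    wins <- wins + (rmse_cal < rmse_pop)
  }
  expect_gt(wins, n_rep / 2)
})

test_that("calibrated predictions respond monotonically to the effects", {
  fit <- dbh_reference_fit()
  d <- ref_records(lh = c(1.5, 3, 6), lcd = 1, p1 = 0)
  cal <- list(u_hat = matrix(c(0.1, 0), 1, 2,
                             dimnames = list("G1", c("b1", "b2"))))
  class(cal) <- "calibration_result"
  expect_true(all(predict_dbh(fit, d, cal) > predict_dbh(fit, d)))
  # reference prediction value at the population level
  expect_equal(predict_dbh(fit, ref_records(lh = 2, lcd = 1, p1 = 0)),
               1.907756, tolerance = 1e-6)
})
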