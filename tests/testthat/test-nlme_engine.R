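test_that("variance functions evaluate per-observation variances", {
  # gamma = 0 reduces both kinds to the homoscedastic model
  vs <- variance_spec("power", "lh", sigma = 0.7, gamma = 0)
  expect_equal(variance_weights(vs, c(1, 4, 9)), rep(0.49, 3))
  ve <- variance_spec("exponential", "lh", sigma = 0.7, gamma = 0)
  expect_equal(variance_weights(ve, c(1, 4, 9)), rep(0.49, 3))
  # reference-model variance at lh = 4 m
  vp <- variance_spec("power", "lh", sigma = 0.3482, gamma = 0.8415)
  expect_equal(variance_weights(vp, 4), 1.250042, tolerance = 1e-6)
  expect_error(variance_weights(vp, c(2, 0)), "positive")
  expect_error(variance_spec("power", sigma = -1), "sigma")
})

test_that("random-effect configuration space enumerates all subsets", {
  expect_length(enumerate_re_configs(model_form("power", "on_b")), 15)
  expect_length(enumerate_re_configs(model_form("power")), 7)
  cfgs <- enumerate_re_configs(model_form("power"))
  expect_equal(cfgs[[1]], "a1")  # size 1 first, lexicographic
  expect_equal(cfgs[[7]], c("a1", "b1", "c1"))
  # sizes are non-decreasing
  expect_true(!is.unsorted(lengths(cfgs)))
})

test_that("NLME estimates recover the generating parameters", {
  sim <- small_sim()
  fit <- small_nlme_fit()
  expect_true(fit$converged)
  # 20 genotypes x 15 trees: the height exponent and the variance exponent
  # are well identified; a1 and c1 trade off along a flat likelihood ridge
  # (lcd is collinear with lh by design), so only predictions pin them down
  re <- abs(fit$fixed - sim$truth$fixed) / abs(sim$truth$fixed)
  expect_lt(re["b1"], 0.20)  # tight recovery needs the study-scale design
  expect_lt(abs(fit$variance$gamma - sim$truth$gamma), 0.2)
  expect_gt(fit$stats$r2, 0.8)
  # information criteria consistency and Psi shape
  expect_equal(fit$ic$k, 4 + 1 + 3 + 1)
  expect_equal(fit$ic$bic - fit$ic$aic, fit$ic$k * (log(fit$ic$n) - 2),
               tolerance = 1e-10)
  expect_equal(fit$psi, t(fit$psi))
  expect_true(all(eigen(fit$psi, symmetric = TRUE)$values >=
                    -1e-10 * sum(diag(fit$psi))))
  expect_setequal(rownames(fit$blups), unique(sim$data$genotype_id))
})

test_that("our likelihood agrees with the reference NLME implementation", {
  skip_if_not_installed("nlme")
  sim <- small_sim()
  fit <- small_nlme_fit()
  d <- as.data.frame(sim$data)
  ref <- suppressWarnings(nlme::nlme(
    dbh ~ a1 * lh^(b1 + b2 * p1) * lcd^c1,
    data = d, fixed = a1 + b1 + b2 + c1 ~ 1,
    random = b1 + b2 ~ 1 | genotype_id,
    weights = nlme::varPower(form = ~lh),
    start = c(a1 = 0.84, b1 = 1.18, b2 = -0.14, c1 = 0.27),
    method = "ML"))
  # both maximize the same linearization-based likelihood but stop at
  # slightly different fixed points of the alternation, so the reported
  # approximate log-likelihoods agree to about a unit, not exactly;
  # coefficient agreement is looser along the flat a1-c1 ridge, so compare
  # the variance exponent and the fitted mean surfaces instead
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 2e-3)
  expect_equal(fit$variance$gamma,
               as.numeric(ref$modelStruct$varStruct[1]), tolerance = 0.05)
  pred_ref1 <- as.numeric(stats::fitted(ref, level = 1))
  expect_lt(sqrt(mean((fit$fitted - pred_ref1)^2)), 0.1)
  pred_ref0 <- as.numeric(stats::predict(ref, level = 0))
  pred_own0 <- predict_dbh(fit, sim$data)
  expect_lt(sqrt(mean((pred_own0 - pred_ref0)^2)), 0.15)
  vc <- nlme::VarCorr(ref)
  psi_diag_ref <- as.numeric(vc[c("b1", "b2"), "Variance"])
  expect_equal(unname(diag(fit$psi)), psi_diag_ref, tolerance = 0.25)
})

test_that("without genotype effects the NLME collapses to the fixed model", {
  set.seed(23)
  n <- 12 * 20
  lh <- runif(n, 1.5, 9); lcd <- runif(n, 0.3, 4)
  pw <- model_form("power")
  d <- tree_data(data.frame(
    genotype_id = rep(sprintf("G%02d", 1:12), each = 20),
    p1 = 0, h = NA, cd = NA, lh = lh, lcd = lcd,
    dbh = predict_mean(pw, c(a1 = 1.2, b1 = 1.1, c1 = 0.3), lh, lcd) +
      rnorm(n, 0, 0.4)))
  fit <- suppressWarnings(
    fit_nlme(d, pw, "b1", variance = "constant"))
  fixed <- fit_fixed_model(d, pw)
  expect_lt(fit$psi[1, 1], 0.01)
  expect_lt(abs(fit$loglik - fixed$ic$loglik), 2)
})

test_that("a single genotype gives a boundary fit with negligible Psi", {
  set.seed(9)
  n <- 40
  lh <- runif(n, 1.5, 9); lcd <- runif(n, 0.3, 4)
  pw <- model_form("power")
  d <- tree_data(data.frame(
    genotype_id = "G1", p1 = 0, h = NA, cd = NA, lh = lh, lcd = lcd,
    dbh = predict_mean(pw, c(a1 = 1.2, b1 = 1.1, c1 = 0.3), lh, lcd) +
      rnorm(n, 0, 0.3)))
  fit <- suppressWarnings(fit_nlme(d, pw, "b1", variance = "constant"))
  expect_lt(fit$psi[1, 1], 0.05)  # u confounded with beta; shrunk away
})

test_that("random-effect search ranks candidates and finds the source", {
  sim <- small_sim()
  res <- search_random_effects(
    sim$data, model_form("power", "on_b"), variance = "power",
    configs = list("b1", "c1", c("b1", "b2")))
  expect_equal(nrow(res$table), 3L)
  expect_true(!is.unsorted(res$ranked$aic))
  # effects were generated on the height exponents
  expect_true("b1" %in% strsplit(res$ranked$config[1], "\\+")[[1]])
})

test_that("likelihood ratio tests follow the chi-square convention", {
  f1 <- list(loglik = -4482.28, ic = list(k = 8))
  f2 <- list(loglik = -4183.37, ic = list(k = 9))
  lrt <- likelihood_ratio_test(f1, f2)
  expect_equal(lrt$statistic, 597.82, tolerance = 1e-10)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p_value, 1e-10)
  # identical fits: statistic 0, p = 1
  same <- likelihood_ratio_test(list(loglik = -10, ic = list(k = 2)),
                                list(loglik = -10, ic = list(k = 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(likelihood_ratio_test(f2, f1), "fewer")
  expect_error(
    likelihood_ratio_test(list(loglik = -5, ic = list(k = 2)),
                          list(loglik = -9, ic = list(k = 3))),
    "negative")
})

test_that("the reference model preset matches its published description", {
  fit <- dbh_reference_fit()
  expect_equal(unname(fit$fixed),
               c(0.8403, 1.1829, -0.1427, 0.2726))
  expect_equal(round(fit$variance$sigma^2, 4), 0.1212)
  expect_equal(2 * fit$variance$gamma, 1.683)
  expect_equal(fit$psi[1, 2], fit$psi[2, 1])
  expect_true(all(eigen(fit$psi, symmetric = TRUE)$values > 0))
})
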