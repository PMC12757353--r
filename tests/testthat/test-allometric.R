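test_that("mean functions evaluate correctly, including dummy shifts", {
  pw <- model_form("power")
  expect_equal(predict_mean(pw, c(a1 = 1, b1 = 1, c1 = 0), lh = 5,
                            lcd = 3.7), 5)
  # density shift on the height exponent (reference coefficients)
  pd <- model_form("power", "on_b")
  pars <- c(a1 = 0.8403, b1 = 1.1829, b2 = -0.1427, c1 = 0.2726)
  expect_equal(predict_mean(pd, pars, lh = 2, lcd = 1, p1 = 0),
               1.907756, tolerance = 1e-6)
  expect_equal(predict_mean(pd, pars, lh = 2, lcd = 1, p1 = 1),
               1.728088, tolerance = 1e-6)
  # zero crown diameter with positive exponent collapses to zero; 0^0 = 1
  expect_equal(predict_mean(pw, c(a1 = 2, b1 = 1, c1 = 0.5), 3, 0), 0)
  expect_equal(predict_mean(pw, c(a1 = 2, b1 = 1, c1 = 0), 3, 0), 6)

  expect_error(predict_mean(pw, c(a1 = 1, b1 = 1), 2, 1), "missing")
  expect_error(predict_mean(pw, c(a1 = 1, b1 = 1, c1 = 1), -2, 1),
               "positive")
  expect_error(model_form("logistic", "on_b"), "power")
})

test_that("power mean is monotone in height for positive exponents", {
  set.seed(17)
  pw <- model_form("power")
  for (rep in 1:25) {
    pars <- c(a1 = runif(1, 0.2, 3), b1 = runif(1, 0.05, 2),
              c1 = runif(1, -1, 1))
    lh <- sort(runif(6, 0.5, 10))
    v <- predict_mean(pw, pars, lh, lcd = runif(1, 0.1, 4))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("logistic mean is bounded by its numerator asymptote", {
  lg <- model_form("logistic")
  pars <- c(a1 = 12, b1 = 2, c1 = 0.4, d1 = 0.3)
  v <- predict_mean(lg, pars, lh = c(1, 5, 50, 500), lcd = c(1, 2, 20, 200))
  expect_true(all(v <= 12))
  expect_true(all(v[1:2] < 12))
  expect_equal(v[4], 12, tolerance = 1e-6)
})

test_that("noiseless model-generated data is recovered by least squares", {
  set.seed(3)
  n <- 150
  lh <- runif(n, 1.5, 9); lcd <- runif(n, 0.3, 4)
  base <- data.frame(genotype_id = "G", p1 = rep(c(0, 1), length.out = n),
                     h = NA, cd = NA, lh = lh, lcd = lcd)
  truths <- list(
    power = list(form = model_form("power"),
                 pars = c(a1 = 1.2, b1 = 1.1, c1 = 0.3)),
    logistic = list(form = model_form("logistic"),
                    pars = c(a1 = 10, b1 = 3, c1 = 0.5, d1 = 0.4)),
    exponential = list(form = model_form("exponential"),
                       pars = c(a1 = 0.8, b1 = -0.25, c1 = -0.1)),
    richards = list(form = model_form("richards"),
                    pars = c(a1 = 9, b1 = 0.3, c1 = 0.2)))
  for (tc in truths) {
    d <- base
    d$dbh <- predict_mean(tc$form, tc$pars, lh, lcd, d$p1)
    fit <- fit_fixed_model(tree_data(d), tc$form)
    expect_equal(unname(fit$params), unname(tc$pars), tolerance = 1e-5)
    expect_equal(fit$stats$r2, 1, tolerance = 1e-9)
  }
})

test_that("noisy power data is recovered within Monte-Carlo tolerance", {
  set.seed(29)
  n <- 2000
  lh <- runif(n, 1.5, 9); lcd <- runif(n, 0.3, 4)
  truth <- c(a1 = 1.2, b1 = 1.1, c1 = 0.3)
  pw <- model_form("power")
  d <- tree_data(data.frame(
    genotype_id = "G", p1 = 0, h = NA, cd = NA, lh = lh, lcd = lcd,
    dbh = predict_mean(pw, truth, lh, lcd) + rnorm(n, 0, 0.5)))
  fit <- fit_fixed_model(d, pw)
  expect_true(all(abs(fit$params - truth) / truth < 0.05))

  # dummy-extended fit recovers the density shift
  d2 <- d
  d2$p1 <- rep(c(0, 1), length.out = n)
  d2$dbh <- predict_mean(model_form("power", "on_b"),
                         c(truth[1:2], b2 = -0.15, c1 = 0.3),
                         lh, lcd, d2$p1) + rnorm(n, 0, 0.3)
  fit2 <- fit_fixed_model(tree_data(d2), model_form("power", "on_b"))
  expect_equal(unname(fit2$params["b2"]), -0.15, tolerance = 0.05)
})

test_that("the generating family wins the AIC comparison on its own data", {
  set.seed(41)
  n <- 800
  lh <- runif(n, 1.5, 9); lcd <- runif(n, 0.3, 4)
  pw <- model_form("power")
  d <- tree_data(data.frame(
    genotype_id = "G", p1 = 0, h = NA, cd = NA, lh = lh, lcd = lcd,
    dbh = predict_mean(pw, c(a1 = 1.2, b1 = 1.1, c1 = 0.3), lh, lcd) +
      rnorm(n, 0, 0.4)))
  fits <- list(power = fit_fixed_model(d, pw),
               exponential = fit_fixed_model(d, model_form("exponential")),
               richards = fit_fixed_model(d, model_form("richards")),
               logistic = fit_fixed_model(d, model_form("logistic")))
  tab <- compare_models(fits, baseline = "power")
  expect_equal(tab$model[1], "power")
})

test_that("relative-change columns follow the percent conventions", {
  base <- list(rmse = 1.1648, r2 = 0.8545, tre = 4.2548)
  new <- list(rmse = 1.0837, r2 = 0.8741, tre = 3.6623)
  imp <- relative_improvement(base, new)
  expect_equal(round(unname(imp["rmse_reduction_pct"]), 2), 6.96)
  expect_equal(round(unname(imp["r2_increase_pct"]), 2), 2.29)
  expect_equal(round(unname(imp["tre_reduction_pct"]), 2), 13.93)
  # identical fits change nothing
  expect_equal(unname(relative_improvement(base, base)), c(0, 0, 0))
})
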