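test_that("single-trial calibration with the base temperature fixed is exact", {
  truth <- cultivar_params("CV1", response_params("gdd", Tb = 8), 900, 1600)
  fx <- const_regime_trials(24, truth)
  fit <- suppressWarnings(   # n = 1: regression metrics absent by design
    calibrate_cultivar(fx$trials, fx$weather, "gdd", fixed = list(Tb = 8)))
  # closed-form inner step: theta equals the accumulated thermal sum at the
  # observed stage dates (16 degree-days per day under a constant 24 C)
  expect_equal(coef(fit)[["theta_flowering"]],
               fx$trials$flowering_dae * 16)
  expect_equal(coef(fit)[["theta_maturity"]],
               fx$trials$maturity_dae * 16)
  expect_equal(fit$metrics_flowering$mad, 0)
  expect_equal(fit$metrics_maturity$mad, 0)
})

test_that("fit metrics match independent arithmetic", {
  ident <- suppressWarnings(fit_metrics(c(90, 100, 110), c(90, 100, 110)))
  expect_equal(ident$mad, 0)
  expect_equal(ident$nrmse, 0)
  expect_equal(ident$alpha, 1)
  expect_equal(ident$beta_intercept, 0)
  expect_equal(ident$r2, 1)

  off <- suppressWarnings(fit_metrics(c(100, 100), c(102, 102)))
  expect_equal(off$mad, 2)
  expect_equal(off$nrmse, 2)

  # hand-computed least squares: Sxx = 200, Sxy = 150, Syy = 114
  hand <- fit_metrics(c(90, 100, 110), c(92, 101, 107))
  expect_equal(hand$mad, 2)
  expect_equal(hand$alpha, 150 / 200)
  expect_equal(hand$beta_intercept, 100 - 0.75 * 100)
  expect_equal(hand$r2, 150^2 / (200 * 114))
  expect_equal(hand$nrmse, 100 * sqrt(14 / 3) / 100)
})

test_that("zero-variance observations drop the regression fields only", {
  expect_warning(m <- fit_metrics(c(100, 100), c(98, 104)), "zero-variance")
  expect_true(is.na(m$alpha) && is.na(m$r2))
  expect_equal(m$mad, 3)
})

test_that("noiseless exponential truth is recovered to within a day", {
  truth <- truth_for("exponential")
  # 40 trials over a 2 deg C span of constant regimes
  fx <- const_regime_trials(seq(24, 26, length.out = 40), truth)
  fit <- suppressWarnings(
    calibrate_cultivar(fx$trials, fx$weather, "exponential", seed = 1))
  expect_true(all(abs(fit$calibration$sim_flowering -
                      fit$calibration$obs_flowering) <= 1))
  expect_true(all(abs(fit$calibration$sim_maturity -
                      fit$calibration$obs_maturity) <= 1))
})

test_that("the returned optimum beats every point of a coarse audit grid", {
  truth <- truth_for("exponential")
  fx <- const_regime_trials(seq(20, 28, length.out = 12), truth)
  fit <- calibrate_cultivar(fx$trials, fx$weather, "exponential", seed = 2)
  obj <- fit$objective_fn
  expect_equal(obj(coef(fit)[c("Tb", "TSEN")])$loss, fit$objective_value,
               tolerance = 1e-9)
  for (tb in seq(5, 15, by = 2.5)) {
    for (ts in seq(0.05, 3, by = 0.5)) {
      expect_lte(fit$objective_value, obj(c(Tb = tb, TSEN = ts))$loss)
    }
  }
})

test_that("calibration is bit-reproducible given the seed", {
  truth <- truth_for("bilinear")
  fx <- const_regime_trials(seq(20, 30, length.out = 15), truth)
  f1 <- calibrate_cultivar(fx$trials, fx$weather, "bilinear", seed = 7)
  f2 <- calibrate_cultivar(fx$trials, fx$weather, "bilinear", seed = 7)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective_value, f2$objective_value)
})

test_that("validating on the calibration set reproduces calibration metrics", {
  truth <- truth_for("gdd")
  fx <- const_regime_trials(seq(21, 27, length.out = 10), truth)
  fit <- calibrate_cultivar(fx$trials, fx$weather, "gdd", seed = 1)
  val <- validate_cultivar(fit, fx$trials, fx$weather)
  m <- fit_metrics(val$obs_maturity, val$sim_maturity)
  expect_equal(m$mad, fit$metrics_maturity$mad)
  expect_equal(m$nrmse, fit$metrics_maturity$nrmse)
})

test_that("empty validation sets are handled with a warning", {
  truth <- truth_for("gdd")
  fx <- const_regime_trials(seq(21, 27, length.out = 5), truth)
  fit <- calibrate_cultivar(fx$trials, fx$weather, "gdd", seed = 1)
  expect_warning(out <- validate_cultivar(fit, fx$trials[0, ], fx$weather),
                 "empty")
  expect_equal(nrow(out), 0)
})

test_that("pheno_fit methods expose coefficients, residuals and predictions", {
  truth <- truth_for("gdd")
  fx <- const_regime_trials(seq(22, 26, length.out = 8), truth)
  fit <- calibrate_cultivar(fx$trials, fx$weather, "gdd", seed = 1)
  expect_named(coef(fit), c("Tb", "theta_flowering", "theta_maturity"))
  r <- residuals(fit)
  expect_equal(dim(r), c(8L, 2L))
  p <- predict(fit, fx$trials, fx$weather)
  expect_equal(p$sim_maturity, fit$calibration$sim_maturity)
  expect_output(print(summary(fit)), "Calibration agreement")
  sims <- simulate(fit, nsim = 2, seed = 3, obs_noise_sd = 1)
  expect_length(sims, 2)
  expect_true(all(sims[[1]]$obs_flowering < sims[[1]]$obs_maturity))
})
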