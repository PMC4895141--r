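test_that("noiseless weather is an exact deterministic sinusoid", {
  cl <- site_climate("s1", annual_mean = 20, annual_amplitude = 6,
                     noise_sd = 0)
  w1 <- generate_weather(cl, 2003, seed = 4)
  w2 <- generate_weather(cl, 2003, seed = 99)  # seed irrelevant without noise
  expect_identical(w1, w2)
  expect_equal(mean((w1$tmin + w1$tmax) / 2), 20, tolerance = 1e-9)
  expect_equal(max((w1$tmin + w1$tmax) / 2), 26, tolerance = 1e-6)
  expect_equal(w1$tmax - w1$tmin, rep(cl$diurnal_range, nrow(w1)))
})

test_that("weather generation is reproducible by seed", {
  cl <- site_climate("s1", annual_mean = 20, noise_sd = 1.5, ar1 = 0.6)
  expect_identical(generate_weather(cl, 2003, seed = 7),
                   generate_weather(cl, 2003, seed = 7))
  expect_false(identical(generate_weather(cl, 2003, seed = 7),
                         generate_weather(cl, 2003, seed = 8)))
})

test_that("the AR(1) noise has the configured autocorrelation", {
  cl <- site_climate("s1", annual_mean = 20, noise_sd = 1, ar1 = 0.6)
  w <- generate_weather(cl, 2001, seed = 21,
                        end_date = as.Date("2010-12-31"))  # 10 years
  tmean <- (w$tmin + w$tmax) / 2
  doy <- seq_along(tmean)
  season <- cl$annual_mean +
    cl$annual_amplitude * cos(2 * pi * (as.integer(format(w$date, "%j")) -
                                        cl$peak_doy) / 365)
  resid <- tmean - season
  expect_equal(stats::cor(resid[-1], resid[-length(resid)]), 0.6,
               tolerance = 0.1)
  expect_equal(stats::sd(resid), 1, tolerance = 0.15)
})

test_that("noiseless observations are reproduced exactly by the truth", {
  d <- trial_design(n_cultivars = 2, trials_range = c(12, 12),
                    target_gst_span = 4, obs_noise_sd = 0, seed = 31)
  ds <- generate_trials(d)
  for (i in seq_len(nrow(ds$trials))) {
    tr <- ds$trials[i, ]
    sim <- simulate_stage_dates(ds$weather[[tr$weather_ref]],
                                tr$emergence_date,
                                ds$truth$params[[tr$cultivar_id]])
    expect_identical(sim$flowering, tr$flowering_dae)
    expect_identical(sim$maturity, tr$maturity_dae)
  }
})

test_that("the design's trial counts and uniqueness constraints hold", {
  d <- trial_design(n_cultivars = 3, trials_range = c(14, 30),
                    target_gst_span = c(3, 6), seed = 17)
  ds <- generate_trials(d)
  counts <- table(ds$trials$cultivar_id)
  expect_length(counts, 3)
  expect_true(all(counts >= 14 & counts <= 30))
  expect_silent(validate_trials(ds$trials))
})

test_that("realized GST span tracks the design target", {
  d <- trial_design(n_cultivars = 1, trials_range = c(40, 40),
                    target_gst_span = 8.2, seed = 5)
  ds <- generate_trials(d)
  tg <- assign_delta_gst(ds$trials, ds$weather)
  expect_equal(max(tg$delta_gst), 8.2, tolerance = 0.5 / 8.2)
})

test_that("datasets round-trip through the on-disk layout", {
  d <- trial_design(n_cultivars = 1, trials_range = c(6, 6),
                    target_gst_span = 3, seed = 23)
  ds <- generate_trials(d)
  dir <- withr::local_tempdir()
  write_synth_dataset(ds, dir)
  tr <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(tr, ds$trials)
  wx <- load_weather_dir(file.path(dir, "weather"))
  expect_setequal(names(wx), names(ds$weather))
  expect_equal(wx[[1]], ds$weather[[names(wx)[1]]])
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$seed, 23)
  back <- read_cultivar_params(file.path(dir, "true_params.dcf"))
  expect_identical(back[[1]]$response, ds$truth$params[[1]]$response)
})

test_that("validation error grows with observation noise", {
  mads <- vapply(c(0, 1, 2, 3), function(noise) {
    per_seed <- vapply(1:5, function(s) {
      d <- trial_design(n_cultivars = 1, trials_range = c(25, 25),
                        target_gst_span = 5, obs_noise_sd = noise,
                        seed = 100 + s)
      tp <- default_truth_params("CV01", model = "gdd", seed = 100 + s)
      ds <- generate_trials(d, true_params = tp)
      tg <- assign_delta_gst(ds$trials, ds$weather)
      sp <- split_experiment(tg, "CV01", 2)
      cal <- ds$trials[ds$trials$trial_id %in% sp$calibration_ids, ]
      val <- ds$trials[ds$trials$trial_id %in% sp$validation_ids, ]
      fit <- calibrate_cultivar(cal, ds$weather, "gdd", seed = 1)
      v <- validate_cultivar(fit, val, ds$weather)
      mean(abs(c(v$sim_flowering - v$obs_flowering,
                 v$sim_maturity - v$obs_maturity)))
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  expect_true(all(diff(mads) > 0))
})
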