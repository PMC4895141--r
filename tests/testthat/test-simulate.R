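test_that("constant-temperature GDD durations follow the thermal sum", {
  cv <- cultivar_params("x", response_params("gdd", Tb = 8), 120, 240)
  w <- make_constant_weather(20, 60)
  s <- simulate_stage_dates(w, w$date[1], cv)
  expect_identical(s$flowering, 10L)  # 120 / (20 - 8)
  expect_identical(s$maturity, 20L)
})

test_that("flowering never comes after maturity", {
  set.seed(31)
  for (k in 1:20) {
    m <- sample(pheno_models(), 1)
    truth <- truth_for(m)
    w <- make_constant_weather(runif(1, 20, 30), 400)
    s <- simulate_stage_dates(w, w$date[1], truth)
    expect_lte(s$flowering, s$maturity)
  }
})

test_that("bilinear development slows above the optimum temperature", {
  cv <- cultivar_params("x", response_params("bilinear", 8, 30, 42), 40, 70)
  s30 <- simulate_stage_dates(make_constant_weather(30, 300),
                              as.Date("2000-01-01"), cv)
  s34 <- simulate_stage_dates(make_constant_weather(34, 300),
                              as.Date("2000-01-01"), cv)
  expect_gt(s34$flowering, s30$flowering)
  expect_gt(s34$maturity, s30$maturity)
})

test_that("weather after the maturity crossing does not affect the result", {
  truth <- truth_for("beta")
  w_long <- make_constant_weather(26, 400)
  s_long <- simulate_stage_dates(w_long, w_long$date[1], truth)
  w_short <- w_long[seq_len(s_long$maturity + 1L), ]
  s_short <- simulate_stage_dates(w_short, w_short$date[1], truth)
  expect_identical(s_long, s_short)
})

test_that("uniform warming below the optimum never lengthens development", {
  for (m in pheno_models()) {
    truth <- truth_for(m)
    base <- 24  # inside (Tb, To) for every family
    s0 <- simulate_stage_dates(make_constant_weather(base, 400),
                               as.Date("2000-01-01"), truth)
    for (delta in c(0.5, 2, 4)) {
      s1 <- simulate_stage_dates(make_constant_weather(base + delta, 400),
                                 as.Date("2000-01-01"), truth)
      expect_lte(s1$flowering, s0$flowering)
      expect_lte(s1$maturity, s0$maturity)
    }
  }
})

test_that("non-maturing series raise a typed error carrying the deficit", {
  cv <- cultivar_params("x", response_params("gdd", Tb = 8), 120, 100000)
  w <- make_constant_weather(20, 100)
  err <- tryCatch(simulate_stage_dates(w, w$date[1], cv),
                  ricepheno_non_maturing = function(e) e)
  expect_s3_class(err, "ricepheno_non_maturing")
  expect_equal(err$deficit, 100000 - 99 * 12)  # 99 accumulating days
  expect_identical(err$stage, "maturity")
})

test_that("growing season temperature is the inclusive window mean", {
  w <- make_constant_weather(25, 200)
  expect_equal(compute_gst(w, w$date[1], w$date[150]), 25)
  w2 <- data.frame(date = as.Date("2000-01-01") + 0:1,
                   tmin = c(15, 25), tmax = c(25, 35))
  expect_equal(compute_gst(w2, w2$date[1], w2$date[2]), 25)
  expect_error(compute_gst(w, w$date[10], w$date[5]), "precede")
  expect_error(compute_gst(w[1:50, ], w$date[1], w$date[100]), "missing")
})

test_that("the window mean of a noiseless sinusoidal year is the annual mean", {
  cl <- site_climate("s", annual_mean = 17.3, noise_sd = 0)
  w <- generate_weather(cl, 2001)  # non-leap year
  expect_equal(compute_gst(w, w$date[1], w$date[365]), 17.3,
               tolerance = 1e-6)
})
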