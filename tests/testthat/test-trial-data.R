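make_trial_df <- function() {
  data.frame(
    trial_id = c("a", "b", "c"), cultivar_id = "CV1",
    site_id = c("s1", "s2", "s3"), year = 2001L,
    emergence_date = as.Date("2001-05-01") + 0:2,
    flowering_dae = c(80L, 85L, 90L), maturity_dae = c(120L, 125L, 130L),
    weather_ref = c("s1_y2001", "s2_y2001", "s3_y2001"),
    stringsAsFactors = FALSE)
}

test_that("trial files round-trip exactly and violations are named", {
  tr <- make_trial_df()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back[names(tr)], tr)

  bad <- tr
  bad$maturity_dae[2] <- 50L  # before flowering
  expect_error(validate_trials(bad), "row\\(s\\) 2.*trial b")

  dup <- tr
  dup$site_id <- "s1"  # duplicate (cultivar, site, year)
  expect_error(validate_trials(dup), "duplicated")
})

test_that("weather files round-trip and enforce gap-free ordering", {
  w <- make_constant_weather(22.5, 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather(w, path)
  expect_equal(read_weather(path), w)

  gap <- w[-4, ]
  expect_error(validate_weather(gap), "gap")
  swapped <- w
  swapped$tmin[3] <- 50
  expect_error(validate_weather(swapped), "tmin > tmax")
})

test_that("cultivar parameter files round-trip all four families exactly", {
  params <- lapply(pheno_models(), truth_for)
  names(params) <- vapply(params, function(p) p$cultivar_id, character(1))
  # distinct ids per family
  for (i in seq_along(params)) params[[i]]$cultivar_id <- paste0("CV", i)
  names(params) <- paste0("CV", seq_along(params))
  path <- withr::local_tempfile(fileext = ".dcf")
  write_cultivar_params(params, path)
  back <- read_cultivar_params(path)
  for (i in seq_along(params)) {
    expect_identical(back[[i]]$response, params[[i]]$response)
    expect_identical(back[[i]]$theta_flowering, params[[i]]$theta_flowering)
    expect_identical(back[[i]]$theta_maturity, params[[i]]$theta_maturity)
  }
})

test_that("delta-GST is the within-cultivar distance to the coolest trial", {
  tr <- make_trial_df()
  # constant-temperature series at 22, 24, 25.5 deg C
  wx <- list(s1_y2001 = make_constant_weather(22, 250, start = "2001-05-01"),
             s2_y2001 = make_constant_weather(24, 250, start = "2001-05-01"),
             s3_y2001 = make_constant_weather(25.5, 250, start = "2001-05-01"))
  tg <- assign_delta_gst(tr, wx)
  expect_equal(tg$gst, c(22, 24, 25.5))
  expect_equal(tg$delta_gst, c(0, 2, 3.5))
  expect_equal(min(tg$delta_gst), 0)
})

test_that("delta-GST is invariant to a uniform temperature shift", {
  tr <- make_trial_df()
  wx <- list(s1_y2001 = make_constant_weather(22, 250, start = "2001-05-01"),
             s2_y2001 = make_constant_weather(24, 250, start = "2001-05-01"),
             s3_y2001 = make_constant_weather(25.5, 250, start = "2001-05-01"))
  shift <- lapply(wx, function(w) {
    w$tmin <- w$tmin + 3.7; w$tmax <- w$tmax + 3.7; w
  })
  expect_equal(assign_delta_gst(tr, wx)$delta_gst,
               assign_delta_gst(tr, shift)$delta_gst)
})

test_that("threshold splits partition trials with an inclusive boundary", {
  tg <- data.frame(trial_id = c("a", "b", "c", "d"), cultivar_id = "CV1",
                   gst = c(20, 20.5, 21.5, 22.5),
                   delta_gst = c(0, 0.5, 1.5, 2.5))
  sp <- split_experiment(tg, "CV1", 1)
  expect_setequal(sp$calibration_ids, c("a", "b"))
  expect_setequal(sp$validation_ids, c("c", "d"))

  # boundary trial goes to calibration
  sp15 <- split_experiment(tg, "CV1", 1.5)
  expect_true("c" %in% sp15$calibration_ids)

  expect_warning(split_experiment(tg, "CV1", 3), "no validation")
  # a subset whose delta-GST values all exceed the threshold
  warm_only <- tg[tg$delta_gst > 1, ]
  expect_error(split_experiment(warm_only, "CV1", 1), "empty calibration")

  all_sp <- split_experiment(tg, "CV1", "all")
  expect_setequal(all_sp$calibration_ids, tg$trial_id)
  expect_length(all_sp$validation_ids, 0)
})

test_that("calibration sets are nested across thresholds", {
  set.seed(11)
  tg <- data.frame(trial_id = sprintf("t%02d", 1:30), cultivar_id = "CV1",
                   gst = 20 + c(0, sort(runif(29, 0, 6))))
  tg$delta_gst <- tg$gst - min(tg$gst)
  sp1 <- split_experiment(tg, "CV1", 1)
  sp2 <- split_experiment(tg, "CV1", 2)
  sp3 <- suppressWarnings(split_experiment(tg, "CV1", 3))
  expect_true(all(sp1$calibration_ids %in% sp2$calibration_ids))
  expect_true(all(sp2$calibration_ids %in% sp3$calibration_ids))
})
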