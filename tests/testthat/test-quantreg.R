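test_that("points on a line are recovered with zero loss at any quantile", {
  x <- 1:10
  y <- 2 * x + 1
  for (tau in c(0.025, 0.3, 0.5, 0.975)) {
    qt <- quantile_trend(x, y, tau)
    expect_equal(qt$slope, 2)
    expect_equal(qt$intercept, 1)
    expect_equal(qt$loss, 0)
  }
})

test_that("small instances match the brute-force check-loss grid oracle", {
  set.seed(13)
  for (rep in 1:6) {
    n <- sample(5:12, 1)
    x <- runif(n, 0, 5)
    y <- 1 + 0.5 * x + rt(n, df = 3)
    tau <- sample(c(0.025, 0.25, 0.5, 0.75, 0.975), 1)
    qt <- quantile_trend(x, y, tau)
    oracle <- grid_rq(x, y, tau)
    # the exact fit can only be at least as good as any grid point
    expect_lte(qt$loss, oracle[["loss"]] + 1e-9)
    # and the grid cannot beat it by more than its own resolution allows
    expect_lt(abs(qt$loss - oracle[["loss"]]), 0.15)
  }
})

test_that("the median fit leaves about half the points strictly below", {
  set.seed(99)
  x <- runif(600, 0, 8)
  y <- 2 + 0.5 * x + rnorm(600, 0, 4)
  qt <- quantile_trend(x, y, 0.5)
  frac <- mean(y < qt$intercept + qt$slope * x)
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("large-sample refinement agrees with exhaustive enumeration", {
  set.seed(5)
  x <- runif(90, 0, 6)          # above the exhaustive-enumeration cutoff
  y <- 1 - 0.3 * x + rnorm(90, 0, 2)
  for (tau in c(0.1, 0.5, 0.9)) {
    fast <- quantile_trend(x, y, tau)
    exact <- local({
      pl <- ricepheno:::pair_lines(x, y, seq_along(x))
      loss <- ricepheno:::cand_losses(pl$a, pl$b, x, y, tau)
      min(loss)
    })
    expect_equal(fast$loss, exact, tolerance = 1e-9)
  }
})

test_that("degenerate predictors and tiny extreme-quantile samples are refused", {
  expect_error(quantile_trend(rep(1, 10), rnorm(10), 0.5), "distinct")
  expect_error(quantile_trend(1:10, rnorm(10), 1.2), "tau")
  set.seed(2)
  x <- runif(20, 0, 5)
  y <- rnorm(20)
  expect_warning(
    expect_warning(tr <- quantile_trends(x, y, taus = c(0.025, 0.5, 0.975)),
                   "absent"),
    "absent")
  expect_true(is.na(tr$slope[tr$tau == 0.025]))
  expect_false(is.na(tr$slope[tr$tau == 0.5]))
})

test_that("crossing quantile lines are reported, ordered lines pass", {
  ordered <- data.frame(tau = c(0.025, 0.5, 0.975),
                        intercept = c(-5, 0, 5), slope = c(1, 1, 1))
  expect_true(check_noncrossing(ordered, c(0, 8)))
  crossing <- data.frame(tau = c(0.025, 0.5), intercept = c(0, 1),
                         slope = c(2, -2))
  expect_message(ok <- check_noncrossing(crossing, c(0, 8)), "cross")
  expect_false(ok)
})
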