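# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# A cultivar observed under a set of constant-temperature regimes, one trial
# per regime, observations simulated from `truth` without noise.
const_regime_trials <- function(temps, truth, n_days = 400,
                                cultivar_id = truth$cultivar_id) {
  weather <- list()
  rows <- vector("list", length(temps))
  for (i in seq_along(temps)) {
    ref <- sprintf("w%03d", i)
    weather[[ref]] <- make_constant_weather(temps[i], n_days)
    sim <- simulate_stage_dates(weather[[ref]], weather[[ref]]$date[1], truth)
    rows[[i]] <- data.frame(
      trial_id = sprintf("t%03d", i), cultivar_id = cultivar_id,
      site_id = ref, year = 2000L + i,
      emergence_date = weather[[ref]]$date[1],
      flowering_dae = sim$flowering, maturity_dae = sim$maturity,
      weather_ref = ref, stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, rows), weather = weather)
}

# Reference truths used in recovery tests: thermal requirements scaled to
# give ~85 / ~128 day durations at 26 deg C under each family.
truth_for <- function(model, cultivar_id = "CVX") {
  default_truth_params(cultivar_id, model = model, seed = 1)[[1]]
}

# Brute-force check-loss grid minimizer (independent oracle for the quantile
# trend): dense grid over (intercept, slope).
grid_rq <- function(x, y, tau, n_grid = 241L) {
  arange <- range(y) + c(-1, 1) * diff(range(y)) * 0.5
  brange <- c(-1, 1) * (diff(range(y)) / max(diff(range(x)), 1e-9) + 1)
  ag <- seq(arange[1], arange[2], length.out = n_grid)
  bg <- seq(brange[1], brange[2], length.out = n_grid)
  best <- c(a = NA_real_, b = NA_real_, loss = Inf)
  for (b in bg) {
    r0 <- y - b * x
    for (a in ag) {
      r <- r0 - a
      l <- sum(r * (tau - (r < 0)))
      if (l < best[["loss"]]) best <- c(a = a, b = b, loss = l)
    }
  }
  best
}
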