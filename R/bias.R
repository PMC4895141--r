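# Percent bias of validated predictions and its trend with warming.

#' Percent bias between simulated and observed stage durations
#'
#' \code{100 * (sim - obs) / obs}; positive values mean the simulated
#' duration is too long (overestimated).
#'
#' @param obs observed duration(s) in days, strictly positive.
#' @param sim simulated duration(s) in days.
#' @return percent bias, same length as the inputs.
#' @examples
#' percent_bias(100, 110)  # +10
#' @export
percent_bias <- function(obs, sim) {
  if (length(obs) != length(sim))
    stop_rp("percent_bias: obs and sim must have equal length")
  if (any(!is.finite(obs)) || any(!is.finite(sim)))
    stop_rp("percent_bias: inputs must be finite")
  if (any(obs <= 0)) stop_rp("percent_bias: obs must be > 0")
  100 * (sim - obs) / obs
}

#' Per-cultivar significance test of the bias trend
#'
#' Ordinary least-squares regression of percent bias on delta-GST with a
#' two-sided t-test of zero slope; the trend is flagged significant at
#' p < 0.05. A one-sample t-test of zero mean bias is reported alongside.
#' The slope test needs at least 4 points with at least 2 distinct x values;
#' otherwise the test is reported absent with a warning.
#'
#' @param delta_gst delta-GST values (deg C).
#' @param pbias percent-bias values.
#' @return one-row data.frame: \code{n, slope, p_value, significant,
#'   mean_bias, mean_bias_p}.
#' @export
cultivar_bias_test <- function(delta_gst, pbias) {
  if (length(delta_gst) != length(pbias))
    stop_rp("cultivar_bias_test: inputs must have equal length")
  n <- length(pbias)
  mean_bias <- if (n) mean(pbias) else NA_real_
  mean_bias_p <- if (n >= 2L && stats::sd(pbias) > 0)
    stats::t.test(pbias)$p.value else NA_real_
  if (n < 4L || length(unique(delta_gst)) < 2L) {
    warn_rp("cultivar_bias_test: slope test reported absent (n=%d, %d distinct delta_gst)",
            n, length(unique(delta_gst)))
    return(data.frame(n = n, slope = NA_real_, p_value = NA_real_,
                      significant = NA, mean_bias = mean_bias,
                      mean_bias_p = mean_bias_p))
  }
  fit <- stats::lm(pbias ~ delta_gst)
  cf <- summary(fit)$coefficients
  slope <- unname(cf["delta_gst", "Estimate"])
  p <- unname(cf["delta_gst", "Pr(>|t|)"])
  data.frame(n = n, slope = slope, p_value = p, significant = p < 0.05,
             mean_bias = mean_bias, mean_bias_p = mean_bias_p)
}

#' Run a full model-mismatch calibration/validation experiment
#'
#' The central in-silico experiment: trials are generated from a known true
#' temperature response (by default a monotone no-optimum family), then each
#' requested model family is auto-calibrated on the cooler trials of every
#' cultivar at each delta-GST threshold, validated on the warmer remainder,
#' and the resulting percent biases are summarized by pooled quantile trends
#' and per-cultivar slope tests. \code{threshold = "all"} is the control in
#' which every trial calibrates and bias is evaluated on the same data.
#'
#' For thresholds 1-3 only validation points enter the quantile trends (they
#' quantify predictive bias); the \code{"all"} control necessarily pools all
#' points.
#'
#' @param design a [trial_design()].
#' @param true_params optional named list of true [cultivar_params()]
#'   (defaults to the generator's monotone truth).
#' @param fitted_models model families to calibrate.
#' @param thresholds delta-GST thresholds; subset of \code{c(1, 2, 3, "all")}.
#' @param taus quantiles for the pooled trends.
#' @param seed experiment seed (overrides the design seed).
#' @param bounds,control passed to [calibrate_cultivar()].
#' @return object of class \code{"mismatch_experiment"}: list with
#'   \code{bias_records} (per trial/model/threshold/stage), per-stage pooled
#'   \code{quantile_trends}, per-cultivar \code{cultivar_tests}, the list of
#'   \code{fits}, the generating \code{truth}, \code{seed} and \code{cells}
#'   bookkeeping.
#' @export
mismatch_experiment <- function(design,
                                true_params = NULL,
                                fitted_models = pheno_models(),
                                thresholds = c(1, 2, 3, "all"),
                                taus = c(0.025, 0.5, 0.975),
                                seed = design$seed,
                                bounds = default_bounds(),
                                control = list()) {
  fitted_models <- match.arg(tolower(fitted_models), pheno_models(),
                             several.ok = TRUE)
  ds <- generate_trials(design, true_params = true_params, seed = seed)
  res <- suppressMessages(run_cells(
    ds$trials, ds$weather, models = fitted_models, thresholds = thresholds,
    taus = taus, seed = seed, bounds = bounds, control = control,
    on_error = "record"))
  structure(c(res, list(truth = ds$truth, seed = as.integer(seed))),
            class = "mismatch_experiment")
}

#' @export
print.mismatch_experiment <- function(x, ...) {
  cat(sprintf("<mismatch experiment: %d bias records, %d cultivar tests, seed %d>\n",
              if (is.null(x$bias_records)) 0L else nrow(x$bias_records),
              if (is.null(x$cultivar_tests)) 0L else nrow(x$cultivar_tests),
              x$seed))
  invisible(x)
}

#' Plot pooled bias trends of a mismatch experiment
#'
#' One panel per model family: validation percent bias against delta-GST with
#' the fitted 0.025/0.5/0.975 quantile-trend lines.
#'
#' @param x a \code{"mismatch_experiment"}.
#' @param stage \code{"maturity"} (default) or \code{"flowering"}.
#' @param threshold which threshold's records to show.
#' @param ... unused.
#' @export
plot.mismatch_experiment <- function(x, stage = "maturity", threshold = "2",
                                     ...) {
  br <- x$bias_records
  br <- br[br$stage == stage & br$threshold == threshold, , drop = FALSE]
  models <- unique(br$model)
  old <- graphics::par(mfrow = c(1, max(1L, length(models))),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (m in models) {
    sub <- br[br$model == m, ]
    graphics::plot(sub$delta_gst, sub$percent_bias, col = "grey60", pch = 16,
                   cex = 0.6, xlab = expression(Delta * "GST (deg C)"),
                   ylab = "Percent bias", main = m)
    graphics::abline(h = 0, col = "grey85")
    tr <- x$quantile_trends
    tr <- tr[tr$model == m & tr$threshold == threshold &
             tr$stage == stage, , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      if (is.na(tr$slope[i])) next
      graphics::abline(tr$intercept[i], tr$slope[i],
                       lty = if (tr$tau[i] == 0.5) 1 else 2)
    }
  }
  invisible(x)
}
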