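# S3 methods for the fitted phenology model object.

#' @export
print.pheno_fit <- function(x, ...) {
  cat(sprintf("Calibrated %s phenology model for cultivar %s\n", x$model,
              x$cultivar_id))
  print(x$params$response)
  cat(sprintf("  thermal requirements: flowering %.2f, maturity %.2f units\n",
              x$params$theta_flowering, x$params$theta_maturity))
  cat(sprintf("  calibration trials: %d | objective: %.3f days^2 | converged: %s\n",
              nrow(x$calibration), x$objective_value, x$converged))
  invisible(x)
}

#' @export
summary.pheno_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.pheno_fit")
}

#' @export
print.summary.pheno_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nCalibration agreement (simulated vs observed DAE):\n")
  cat("  flowering: "); print(f$metrics_flowering)
  cat("  maturity:  "); print(f$metrics_maturity)
  invisible(x)
}

#' @export
coef.pheno_fit <- function(object, ...) {
  rp <- object$params$response
  out <- c(Tb = rp$Tb, To = rp$To, Tc = rp$Tc, TSEN = rp$TSEN,
           theta_flowering = object$params$theta_flowering,
           theta_maturity = object$params$theta_maturity)
  unlist(out)
}

#' Predict stage dates for new trials from a calibrated fit
#'
#' @param object a \code{"pheno_fit"}.
#' @param trials trial data.frame (only \code{emergence_date} and
#'   \code{weather_ref} are used).
#' @param weather named weather list.
#' @param ... unused.
#' @return data.frame \code{trial_id, sim_flowering, sim_maturity}; trials
#'   that never mature within their weather span get \code{NA} with a
#'   warning.
#' @export
predict.pheno_fit <- function(object, trials, weather, ...) {
  trials <- validate_trials(trials)
  sims <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    tryCatch(simulate_stage_dates(weather[[tr$weather_ref]],
                                  tr$emergence_date, object$params),
             ricepheno_non_maturing = function(e) list(flowering = NA_integer_,
                                                       maturity = NA_integer_))
  })
  out <- data.frame(trial_id = trials$trial_id,
                    sim_flowering = vapply(sims, `[[`, integer(1), "flowering"),
                    sim_maturity = vapply(sims, `[[`, integer(1), "maturity"),
                    stringsAsFactors = FALSE)
  if (anyNA(out$sim_maturity))
    warn_rp("predict.pheno_fit: %d trial(s) non-maturing (NA)",
            sum(is.na(out$sim_maturity)))
  out
}

#' @export
residuals.pheno_fit <- function(object, ...) {
  with(object$calibration,
       cbind(flowering = sim_flowering - obs_flowering,
             maturity = sim_maturity - obs_maturity))
}

#' Simulate replicate observed stage dates from a calibrated fit
#'
#' Draws \code{nsim} replicates of the calibration trials' stage dates by
#' adding rounded Gaussian observation noise to the model-simulated DAE,
#' mimicking field observation error.
#'
#' @param object a \code{"pheno_fit"}.
#' @param nsim number of replicate data sets.
#' @param seed RNG seed.
#' @param obs_noise_sd observation noise standard deviation in days.
#' @param ... unused.
#' @return list of \code{nsim} data.frames shaped like
#'   \code{object$calibration}.
#' @export
simulate.pheno_fit <- function(object, nsim = 1, seed = 1L,
                               obs_noise_sd = 2, ...) {
  base <- object$calibration
  with_seed(seed, lapply(seq_len(nsim), function(k) {
    out <- base
    out$obs_flowering <- pmax(1L, as.integer(round(
      base$sim_flowering + stats::rnorm(nrow(base), 0, obs_noise_sd))))
    out$obs_maturity <- pmax(out$obs_flowering + 1L, as.integer(round(
      base$sim_maturity + stats::rnorm(nrow(base), 0, obs_noise_sd))))
    out
  }))
}

#' Plot calibration agreement of a fitted phenology model
#'
#' Observed vs simulated DAE for flowering and maturity with the 1:1 line.
#'
#' @param x a \code{"pheno_fit"}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pheno_fit <- function(x, ...) {
  cal <- x$calibration
  rng <- range(cal$obs_flowering, cal$obs_maturity, cal$sim_flowering,
               cal$sim_maturity)
  graphics::plot(cal$obs_flowering, cal$sim_flowering, xlim = rng, ylim = rng,
                 pch = 1, col = "grey55",
                 xlab = "Observed DAE", ylab = "Simulated DAE",
                 main = sprintf("%s model, cultivar %s", x$model,
                                x$cultivar_id), ...)
  graphics::points(cal$obs_maturity, cal$sim_maturity, pch = 16,
                   col = "grey25")
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("flowering", "maturity"),
                   pch = c(1, 16), col = c("grey55", "grey25"), bty = "n")
  invisible(x)
}
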