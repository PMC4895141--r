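#' Goodness-of-fit metrics for simulated vs observed stage durations
#'
#' Computes the standard agreement summary between simulated and observed
#' days after emergence: mean absolute deviation (MAD, days), normalized root
#' mean square error (NRMSE, percent of the mean observed value), and the
#' ordinary least-squares regression of simulated on observed values (slope
#' \code{alpha}, intercept \code{beta_intercept} in days, and R squared).
#'
#' @param obs observed durations (days), length >= 1.
#' @param sim simulated durations (days), same length.
#' @return object of class \code{"fit_metrics"}: list with \code{n, mad,
#'   alpha, beta_intercept, r2, nrmse}. If the observations have zero
#'   variance (or \code{n < 2}) the regression fields are \code{NA} and a
#'   warning is raised; MAD and NRMSE are still computed.
#' @examples
#' fit_metrics(c(90, 100, 110), c(92, 101, 107))
#' @export
fit_metrics <- function(obs, sim) {
  if (length(obs) != length(sim) || !length(obs))
    stop_rp("fit_metrics: obs and sim must be equal-length, non-empty vectors")
  if (anyNA(obs) || anyNA(sim)) stop_rp("fit_metrics: NA values not allowed")
  mad <- mean(abs(sim - obs))
  nrmse <- 100 * sqrt(mean((sim - obs)^2)) / mean(obs)
  alpha <- beta <- r2 <- NA_real_
  if (length(obs) >= 2L && stats::var(obs) > 0) {
    fit <- stats::lm(sim ~ obs)
    alpha <- unname(stats::coef(fit)[2L])
    beta <- unname(stats::coef(fit)[1L])
    r2 <- summary(fit)$r.squared
  } else {
    warn_rp("fit_metrics: zero-variance observations; regression fields reported absent")
  }
  structure(list(n = length(obs), mad = mad, alpha = alpha,
                 beta_intercept = beta, r2 = r2, nrmse = nrmse),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("n=%d  MAD=%.2f d  alpha=%.3f  beta=%.2f d  R2=%.3f  NRMSE=%.2f%%\n",
              x$n, x$mad, x$alpha, x$beta_intercept, x$r2, x$nrmse))
  invisible(x)
}

as_row.fit_metrics <- function(x) {
  data.frame(n = x$n, MAD = x$mad, alpha = x$alpha, beta = x$beta_intercept,
             R2 = x$r2, NRMSE = x$nrmse)
}
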