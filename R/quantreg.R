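# Check-loss (quantile) regression of percent bias on delta-GST.
#
# The minimizer of the check loss sum rho_tau(y - a - b x) over (a, b) is a
# linear program; with one covariate plus intercept an optimal basic solution
# interpolates two data points with distinct x. The fit therefore enumerates
# interpolating lines: exhaustively for small n, and for large n via an
# active-set refinement that repeatedly enumerates pairs among the points
# nearest the current line (the loss is convex, so accepted moves strictly
# decrease it and the iteration terminates). Among loss ties the
# lexicographically smallest (intercept, slope) is reported, which makes the
# fit deterministic.

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# evaluate check loss for candidate lines (a, b vectors) against (x, y)
cand_losses <- function(a, b, x, y, tau) {
  vapply(seq_along(a), function(k) check_loss(y - a[k] - b[k] * x, tau),
         numeric(1))
}

# all interpolating lines through pairs of points drawn from index set `idx`
pair_lines <- function(x, y, idx) {
  if (length(idx) < 2L) return(NULL)
  cmb <- utils::combn(idx, 2L)
  xi <- x[cmb[1L, ]]; xj <- x[cmb[2L, ]]
  keep <- xi != xj
  if (!any(keep)) return(NULL)
  b <- (y[cmb[2L, keep]] - y[cmb[1L, keep]]) / (xj[keep] - xi[keep])
  a <- y[cmb[1L, keep]] - b * xi[keep]
  list(a = a, b = b)
}

#' Quantile-regression trend of percent bias against delta-GST
#'
#' Fits the straight line minimizing the check loss
#' \eqn{\sum_i \rho_\tau(y_i - a - b x_i)} with
#' \eqn{\rho_\tau(u) = u (\tau - 1\{u < 0\})}, i.e. the \eqn{\tau}-quantile
#' regression of \code{y} on \code{x}. Used with
#' \eqn{\tau \in \{0.025, 0.5, 0.975\}} to track the lower, middle and upper
#' envelope of prediction bias as the growing season warms.
#'
#' @param x predictor (delta-GST, deg C); needs at least 3 distinct values.
#' @param y response (percent bias).
#' @param tau quantile in (0, 1).
#' @return object of class \code{"quantile_trend"}: list with \code{tau},
#'   \code{intercept} (percent), \code{slope} (percent per deg C),
#'   \code{loss} and \code{n}.
#' @examples
#' qt <- quantile_trend(1:10, 2 * (1:10) + 1, tau = 0.5)
#' c(qt$intercept, qt$slope)  # 1, 2
#' @export
quantile_trend <- function(x, y, tau) {
  if (length(x) != length(y) || anyNA(x) || anyNA(y))
    stop_rp("quantile_trend: x and y must be equal-length without NA")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop_rp("quantile_trend: tau must lie in (0, 1)")
  if (length(unique(x)) < 3L)
    stop_rp("quantile_trend: need at least 3 distinct x values (got %d)",
            length(unique(x)))
  n <- length(x)
  pick_best <- function(a, b) {
    loss <- cand_losses(a, b, x, y, tau)
    m <- min(loss)
    tied <- which(loss <= m + 1e-9 * max(1, abs(m)))
    o <- tied[order(a[tied], b[tied])][1L]
    list(a = a[o], b = b[o], loss = loss[o])
  }
  if (n <= 80L) {
    pl <- pair_lines(x, y, seq_len(n))
    best <- pick_best(pl$a, pl$b)
  } else {
    # warm start: OLS line, then active-set pair refinement
    X <- cbind(1, x)
    beta <- stats::lm.fit(X, y)$coefficients
    best <- list(a = beta[1L], b = beta[2L],
                 loss = check_loss(y - beta[1L] - beta[2L] * x, tau))
    m_near <- 35L
    repeat {
      r <- abs(y - best$a - best$b * x)
      idx <- order(r)[seq_len(min(m_near, n))]
      pl <- pair_lines(x, y, idx)
      cand <- pick_best(pl$a, pl$b)
      if (cand$loss < best$loss - 1e-12 * max(1, best$loss)) {
        best <- cand
        m_near <- 35L
      } else if (m_near < 150L) {
        m_near <- 150L            # widen the neighbourhood once before stopping
      } else break
    }
  }
  structure(list(tau = tau, intercept = unname(best$a),
                 slope = unname(best$b), loss = unname(best$loss), n = n),
            class = "quantile_trend")
}

#' @export
print.quantile_trend <- function(x, ...) {
  cat(sprintf("<tau=%.3f quantile trend: bias = %.3f %+.3f * dGST  (n=%d)>\n",
              x$tau, x$intercept, x$slope, x$n))
  invisible(x)
}

#' Fit the three bias-envelope quantile trends
#'
#' Convenience wrapper fitting [quantile_trend()] at the lower, middle and
#' upper quantiles (0.025, 0.5, 0.975 by default). The extreme quantiles are
#' poorly determined in small samples and are reported absent (with a
#' warning) below \code{min_extreme_n} points.
#'
#' @param x,y as in [quantile_trend()].
#' @param taus quantiles to fit.
#' @param min_extreme_n minimum points required for taus outside
#'   \code{[0.25, 0.75]}.
#' @return data.frame \code{tau, intercept, slope, n} (absent fits as NA).
#' @export
quantile_trends <- function(x, y, taus = c(0.025, 0.5, 0.975),
                            min_extreme_n = 40L) {
  rows <- lapply(taus, function(tau) {
    extreme <- tau < 0.25 || tau > 0.75
    if (extreme && length(x) < min_extreme_n) {
      warn_rp("quantile_trends: tau=%.3f reported absent (n=%d < %d points)",
              tau, length(x), min_extreme_n)
      return(data.frame(tau = tau, intercept = NA_real_, slope = NA_real_,
                        n = length(x)))
    }
    qt <- quantile_trend(x, y, tau)
    data.frame(tau = tau, intercept = qt$intercept, slope = qt$slope,
               n = qt$n)
  })
  do.call(rbind, rows)
}

#' Check the non-crossing property of fitted quantile trends
#'
#' Quantile-regression lines fitted independently at several quantiles can
#' cross in small samples. This checks whether the lines for increasing tau
#' remain ordered over the observed x range and logs (messages) any crossing
#' rather than hiding it.
#'
#' @param trends data.frame from [quantile_trends()] (NA rows skipped).
#' @param xrange numeric length-2 range of delta-GST over which to check.
#' @return logical: TRUE if no crossing was found.
#' @export
check_noncrossing <- function(trends, xrange) {
  tr <- trends[!is.na(trends$slope), , drop = FALSE]
  tr <- tr[order(tr$tau), , drop = FALSE]
  ok <- TRUE
  if (nrow(tr) < 2L) return(ok)
  for (i in seq_len(nrow(tr) - 1L)) {
    lo <- tr[i, ]; hi <- tr[i + 1L, ]
    at <- function(t, xx) t$intercept + t$slope * xx
    for (xx in xrange) {
      if (at(hi, xx) < at(lo, xx) - 1e-9) {
        message(sprintf(
          "quantile trends cross: tau=%.3f above tau=%.3f at dGST=%.2f",
          lo$tau, hi$tau, xx))
        ok <- FALSE
      }
    }
  }
  ok
}
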