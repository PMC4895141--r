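#' Simulate days after emergence to flowering and maturity
#'
#' Accumulates the daily development rate (driven by the daily mean
#' temperature \code{(tmin + tmax)/2}) from the day after emergence onward.
#' The day after emergence is DAE 1. A stage is reached on the first day on
#' which the cumulative sum meets or exceeds the stage's thermal requirement
#' (first-crossing rule, whole days).
#'
#' @param weather daily weather series covering emergence through at least the
#'   maturity crossing.
#' @param emergence emergence date (coercible to Date), within the weather
#'   span.
#' @param cultivar a [cultivar_params()] object.
#' @return list with integer elements \code{flowering} and \code{maturity}
#'   (days after emergence). \code{flowering <= maturity} always.
#' @section Non-maturing series: if the accumulation never reaches a threshold
#'   within the weather span an error of class
#'   \code{"ricepheno_non_maturing"} is signalled; its \code{deficit} field
#'   carries the missing development units.
#' @examples
#' cv <- cultivar_params("demo", response_params("gdd", Tb = 8), 120, 240)
#' w <- make_constant_weather(20, 60)
#' simulate_stage_dates(w, w$date[1], cv)  # flowering at DAE 10
#' @export
simulate_stage_dates <- function(weather, emergence, cultivar) {
  if (!inherits(cultivar, "cultivar_params"))
    stop_rp("simulate_stage_dates: `cultivar` must be a cultivar_params object")
  weather <- validate_weather(weather)
  emergence <- as.Date(emergence)
  if (emergence < weather$date[1L] || emergence > weather$date[nrow(weather)])
    stop_rp("simulate_stage_dates: emergence %s outside weather span [%s, %s]",
            emergence, weather$date[1L], weather$date[nrow(weather)])
  after <- weather[weather$date > emergence, , drop = FALSE]
  if (nrow(after) == 0L)
    stop_rp("simulate_stage_dates: no weather after emergence %s", emergence)
  tmean <- (after$tmin + after$tmax) / 2
  cum <- cumsum(daily_rate(tmean, cultivar$response))
  dae <- function(theta, stage) {
    i <- which(cum >= theta)
    if (!length(i)) {
      cond <- structure(
        class = c("ricepheno_non_maturing", "error", "condition"),
        list(message = sprintf(
               "development never reaches %s threshold (%.3f units short after %d days)",
               stage, theta - cum[length(cum)], length(cum)),
             call = NULL,
             deficit = theta - cum[length(cum)],
             stage = stage))
      stop(cond)
    }
    i[1L]
  }
  f <- dae(cultivar$theta_flowering, "flowering")
  m <- dae(cultivar$theta_maturity, "maturity")
  list(flowering = as.integer(f), maturity = as.integer(m))
}
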