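#' Validate a daily weather series
#'
#' A weather series is a data.frame with columns \code{date} (class Date),
#' \code{tmin} and \code{tmax} (deg C). Dates must be strictly increasing,
#' daily and gap-free; \code{tmin <= tmax} everywhere.
#'
#' @param weather data.frame to check.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_weather <- function(weather) {
  need <- c("date", "tmin", "tmax")
  if (!is.data.frame(weather) || !all(need %in% names(weather)))
    stop_rp("weather must be a data.frame with columns date, tmin, tmax")
  weather$date <- as.Date(weather$date)
  if (anyNA(weather$date)) stop_rp("weather: unparseable dates")
  if (nrow(weather) > 1L) {
    d <- diff(as.integer(weather$date))
    if (any(d != 1L)) {
      bad <- which(d != 1L)[1L]
      stop_rp("weather: dates must be consecutive days; gap/disorder after row %d (%s)",
              bad, weather$date[bad])
    }
  }
  for (nm in c("tmin", "tmax")) {
    if (!is.numeric(weather[[nm]]) || anyNA(weather[[nm]]) ||
        any(!is.finite(weather[[nm]])))
      stop_rp("weather: column %s must be finite numeric", nm)
  }
  bad <- which(weather$tmin > weather$tmax)
  if (length(bad))
    stop_rp("weather: tmin > tmax on %d row(s), first at row %d (%s)",
            length(bad), bad[1L], weather$date[bad[1L]])
  weather[need]
}

#' Build a constant-temperature weather series
#'
#' Convenience generator for controlled regimes (e.g. constant-temperature
#' recovery experiments): every day has the same mean temperature.
#'
#' @param tmean daily mean temperature (deg C).
#' @param n_days number of days.
#' @param diurnal_range tmax - tmin spread around the mean (deg C, >= 0).
#' @param start first date.
#' @return a weather data.frame.
#' @export
make_constant_weather <- function(tmean, n_days, diurnal_range = 0,
                                  start = as.Date("2000-01-01")) {
  stopifnot(is.numeric(tmean), length(tmean) == 1L, n_days >= 1L,
            diurnal_range >= 0)
  validate_weather(data.frame(
    date = seq(as.Date(start), by = "day", length.out = n_days),
    tmin = tmean - diurnal_range / 2,
    tmax = tmean + diurnal_range / 2))
}

#' Read / write a daily weather file
#'
#' Delimited text, one row per day with header \code{date,tmin,tmax};
#' ISO-8601 dates, decimal point. Lines starting with \code{#} are treated as
#' comments.
#'
#' @param path file path.
#' @return \code{read_weather}: validated weather data.frame.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop_rp("weather file not found: %s", path)
  w <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_weather(w)
}

#' @rdname read_weather
#' @param weather weather data.frame.
#' @param header_comment optional character vector written as leading
#'   \code{#} comment lines.
#' @export
write_weather <- function(weather, path, header_comment = NULL) {
  weather <- validate_weather(weather)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (length(header_comment))
    writeLines(paste0("# ", header_comment), con)
  out <- data.frame(date = format(weather$date, "%Y-%m-%d"),
                    tmin = num_chr(weather$tmin),
                    tmax = num_chr(weather$tmax))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Growing season temperature
#'
#' Arithmetic mean of the daily mean temperature \code{(tmin + tmax)/2} over
#' the window from emergence to maturity, both endpoints included.
#'
#' @param weather daily weather series covering the window.
#' @param emergence,maturity calendar dates (coercible to Date).
#' @return mean temperature in deg C.
#' @examples
#' w <- make_constant_weather(25, 120)
#' compute_gst(w, w$date[1], w$date[100])  # 25
#' @export
compute_gst <- function(weather, emergence, maturity) {
  weather <- validate_weather(weather)
  emergence <- as.Date(emergence); maturity <- as.Date(maturity)
  if (!(emergence < maturity))
    stop_rp("compute_gst: emergence (%s) must precede maturity (%s)",
            emergence, maturity)
  window <- seq(emergence, maturity, by = "day")
  idx <- match(window, weather$date)
  if (anyNA(idx))
    stop_rp("compute_gst: weather series is missing %d day(s) in [%s, %s]",
            sum(is.na(idx)), emergence, maturity)
  mean((weather$tmin[idx] + weather$tmax[idx]) / 2)
}
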