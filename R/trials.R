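# Trial records: data model, file I/O, GST / delta-GST construction and
# calibration/validation splitting.

TRIAL_COLUMNS <- c("trial_id", "cultivar_id", "site_id", "year",
                   "emergence_date", "flowering_dae", "maturity_dae",
                   "weather_ref")

#' Validate a trial table
#'
#' Enforces the trial invariants: \code{0 < flowering_dae < maturity_dae} per
#' trial, and unique (cultivar, site, year) combinations (one combination is
#' one trial). Violations are reported with row numbers and trial ids.
#'
#' @param trials data.frame with columns \code{trial_id, cultivar_id, site_id,
#'   year, emergence_date, flowering_dae, maturity_dae, weather_ref}. Optional
#'   extra columns (e.g. transplanting dates) are carried through untouched.
#' @return the validated data.frame with \code{emergence_date} as Date and
#'   DAE columns as integer.
#' @export
validate_trials <- function(trials) {
  if (!is.data.frame(trials) || !all(TRIAL_COLUMNS %in% names(trials)))
    stop_rp("trials must be a data.frame with columns: %s",
            paste(TRIAL_COLUMNS, collapse = ", "))
  trials$emergence_date <- as.Date(trials$emergence_date)
  if (anyNA(trials$emergence_date))
    stop_rp("trials: unparseable emergence_date values")
  trials$flowering_dae <- as.integer(trials$flowering_dae)
  trials$maturity_dae <- as.integer(trials$maturity_dae)
  trials$year <- as.integer(trials$year)
  bad <- which(!(trials$flowering_dae > 0L &
                 trials$flowering_dae < trials$maturity_dae))
  if (length(bad))
    stop_rp("trials: need 0 < flowering_dae < maturity_dae; violated at row(s) %s (trial %s)",
            paste(bad, collapse = ", "),
            paste(trials$trial_id[bad], collapse = ", "))
  key <- paste(trials$cultivar_id, trials$site_id, trials$year, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop_rp("trials: duplicated (cultivar, site, year) at row(s) %s (trial %s)",
            paste(dup, collapse = ", "),
            paste(trials$trial_id[dup], collapse = ", "))
  if (anyDuplicated(trials$trial_id))
    stop_rp("trials: trial_id values must be unique")
  trials
}

#' Read / write a trial file
#'
#' Delimited text with the canonical header
#' \code{trial_id,cultivar_id,site_id,year,emergence_date,flowering_dae,maturity_dae,weather_ref}.
#' All invariants are enforced on load; a write/read round trip reproduces the
#' records exactly.
#'
#' @param path file path.
#' @return \code{read_trials}: validated trial data.frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop_rp("trial file not found: %s", path)
  tr <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_trials(tr)
}

#' @rdname read_trials
#' @param trials trial data.frame.
#' @param header_comment optional character vector of leading \code{#} lines.
#' @export
write_trials <- function(trials, path, header_comment = NULL) {
  trials <- validate_trials(trials)
  out <- trials[TRIAL_COLUMNS]
  out$emergence_date <- format(out$emergence_date, "%Y-%m-%d")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (length(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write cultivar parameter files
#'
#' Flat key-value blocks (Debian-control style, one cultivar per block) that
#' round-trip [cultivar_params()] objects exactly.
#'
#' @param path file path.
#' @return \code{read_cultivar_params}: named list of [cultivar_params()].
#' @export
read_cultivar_params <- function(path) {
  if (!file.exists(path)) stop_rp("cultivar parameter file not found: %s", path)
  m <- read.dcf(path)
  out <- lapply(seq_len(nrow(m)), function(i) {
    row <- as.list(m[i, ])
    row <- row[!vapply(row, is.na, logical(1))]
    num <- function(nm) if (is.null(row[[nm]])) NULL else as.numeric(row[[nm]])
    rp <- response_params(row$model, Tb = num("Tb"), To = num("To"),
                          Tc = num("Tc"), TSEN = num("TSEN"))
    cultivar_params(row$cultivar_id, rp, num("theta_flowering"),
                    num("theta_maturity"))
  })
  names(out) <- vapply(out, function(p) p$cultivar_id, character(1))
  out
}

#' @rdname read_cultivar_params
#' @param params a [cultivar_params()] object or list of them.
#' @export
write_cultivar_params <- function(params, path) {
  if (inherits(params, "cultivar_params")) params <- list(params)
  rows <- lapply(params, function(p) {
    rp <- p$response
    v <- c(cultivar_id = p$cultivar_id, model = rp$model,
           Tb = num_chr(rp$Tb),
           To = if (!is.null(rp$To)) num_chr(rp$To),
           Tc = if (!is.null(rp$Tc)) num_chr(rp$Tc),
           TSEN = if (!is.null(rp$TSEN)) num_chr(rp$TSEN),
           theta_flowering = num_chr(p$theta_flowering),
           theta_maturity = num_chr(p$theta_maturity))
    v
  })
  all_fields <- unique(unlist(lapply(rows, names)))
  m <- do.call(rbind, lapply(rows, function(r) r[all_fields]))
  colnames(m) <- all_fields
  write.dcf(m, path)
  invisible(path)
}

#' Growing-season temperature and delta-GST per trial
#'
#' Computes each trial's growing season temperature (GST: mean daily
#' temperature from emergence to *observed* maturity, endpoints included) and
#' the within-cultivar delta-GST: the trial's GST minus the lowest GST among
#' all trials of the same cultivar. The coolest trial of every cultivar
#' therefore has \code{delta_gst = 0}.
#'
#' @param trials validated trial data.frame.
#' @param weather named list of weather data.frames, keyed by
#'   \code{weather_ref}.
#' @return data.frame \code{trial_id, cultivar_id, gst, delta_gst}.
#' @export
assign_delta_gst <- function(trials, weather) {
  trials <- validate_trials(trials)
  miss <- setdiff(unique(trials$weather_ref), names(weather))
  if (length(miss))
    stop_rp("assign_delta_gst: missing weather series: %s",
            paste(miss, collapse = ", "))
  gst <- vapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    compute_gst(weather[[tr$weather_ref]], tr$emergence_date,
                tr$emergence_date + tr$maturity_dae)
  }, numeric(1))
  out <- data.frame(trial_id = trials$trial_id,
                    cultivar_id = trials$cultivar_id,
                    gst = gst, stringsAsFactors = FALSE)
  out$delta_gst <- gst - stats::ave(gst, trials$cultivar_id, FUN = min)
  singles <- names(which(table(trials$cultivar_id) == 1L))
  if (length(singles))
    message(sprintf("assign_delta_gst: cultivar(s) %s have a single trial; delta_gst fixed at 0",
                    paste(singles, collapse = ", ")))
  out
}

#' Split a cultivar's trials into calibration and validation sets
#'
#' Implements the delta-GST calibration experiments: trials with
#' \code{delta_gst <= threshold} (boundary inclusive) calibrate the model and
#' the warmer remainder validates it. \code{threshold = "all"} is the control
#' design in which every trial calibrates and the validation set is empty.
#'
#' @param trials_gst output of [assign_delta_gst()] (columns \code{trial_id,
#'   cultivar_id, delta_gst}).
#' @param cultivar_id cultivar to split.
#' @param threshold numeric delta-GST threshold in deg C (canonically 1, 2 or
#'   3) or the string \code{"all"}.
#' @return object of class \code{"calibration_experiment"}: list with
#'   \code{cultivar_id}, \code{threshold}, \code{calibration_ids},
#'   \code{validation_ids}.
#' @export
split_experiment <- function(trials_gst, cultivar_id, threshold) {
  stopifnot(all(c("trial_id", "cultivar_id", "delta_gst") %in%
                names(trials_gst)))
  sub <- trials_gst[trials_gst$cultivar_id == cultivar_id, , drop = FALSE]
  if (!nrow(sub))
    stop_rp("split_experiment: no trials for cultivar %s", cultivar_id)
  if (identical(threshold, "all") || identical(threshold, "ALL")) {
    cal <- sub$trial_id
    val <- character(0)
    threshold <- "all"
  } else {
    threshold <- as.numeric(threshold)
    if (!is.finite(threshold) || threshold <= 0)
      stop_rp("split_experiment: threshold must be positive or \"all\"")
    in_cal <- sub$delta_gst <= threshold
    if (!any(in_cal))
      stop_rp("split_experiment: empty calibration set for cultivar %s at threshold %g; use a larger threshold",
              cultivar_id, threshold)
    cal <- sub$trial_id[in_cal]
    val <- sub$trial_id[!in_cal]
    if (!length(val))
      warn_rp("split_experiment: cultivar %s has no validation trials at threshold %g (all delta_gst <= threshold)",
              cultivar_id, threshold)
  }
  structure(list(cultivar_id = cultivar_id, threshold = threshold,
                 calibration_ids = cal, validation_ids = val),
            class = "calibration_experiment")
}

#' @export
print.calibration_experiment <- function(x, ...) {
  cat(sprintf("<calibration experiment: cultivar %s, threshold %s | %d calibration, %d validation trials>\n",
              x$cultivar_id, as.character(x$threshold),
              length(x$calibration_ids), length(x$validation_ids)))
  invisible(x)
}
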