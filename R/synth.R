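# Synthetic trial and daily-weather generator with known ground truth.
#
# Emulates the structure of a multi-site, multi-year rice trial network:
# around 19 cultivars with 14-260 trials each, whose growing season
# temperatures (GST) span roughly 2-8 deg C within a cultivar. GST variation
# is induced both by site climate differences (sites spaced in annual mean
# temperature) and by emergence-date spread within sites.

#' Site climate description for the weather generator
#'
#' @param site_id character identifier.
#' @param annual_mean annual mean temperature (deg C).
#' @param annual_amplitude seasonal half-amplitude of the sinusoid (deg C).
#' @param diurnal_range tmax - tmin spread (deg C, > 0).
#' @param noise_sd stationary standard deviation of the AR(1) day-to-day
#'   temperature noise (deg C, >= 0).
#' @param ar1 lag-1 autocorrelation of the noise, in [0, 1).
#' @param peak_doy day of year at which the seasonal cycle peaks.
#' @return object of class \code{"site_climate"}.
#' @export
site_climate <- function(site_id, annual_mean, annual_amplitude = 7,
                         diurnal_range = 8, noise_sd = 1.5, ar1 = 0.6,
                         peak_doy = 200) {
  stopifnot(noise_sd >= 0, diurnal_range > 0, ar1 >= 0, ar1 < 1)
  structure(list(site_id = as.character(site_id),
                 annual_mean = annual_mean,
                 annual_amplitude = annual_amplitude,
                 diurnal_range = diurnal_range, noise_sd = noise_sd,
                 ar1 = ar1, peak_doy = peak_doy),
            class = "site_climate")
}

#' Generate a daily weather series for a site
#'
#' The daily mean temperature is a seasonal sinusoid
#' \code{annual_mean + annual_amplitude * cos(2 * pi * (doy - peak_doy) / 365)}
#' plus stationary AR(1) noise; \code{tmin}/\code{tmax} sit half the diurnal
#' range below/above the mean. Reproducible given the seed.
#'
#' @param climate a [site_climate()].
#' @param year first calendar year of the series.
#' @param seed RNG seed.
#' @param end_date last day (default: Dec 31 of \code{year}).
#' @return validated weather data.frame.
#' @export
generate_weather <- function(climate, year, seed = 1L,
                             end_date = as.Date(sprintf("%d-12-31", year))) {
  stopifnot(inherits(climate, "site_climate"))
  dates <- seq(as.Date(sprintf("%d-01-01", year)), as.Date(end_date),
               by = "day")
  doy <- as.integer(format(dates, "%j")) +
    365 * (as.integer(format(dates, "%Y")) - year)
  tmean <- climate$annual_mean +
    climate$annual_amplitude * cos(2 * pi * (doy - climate$peak_doy) / 365)
  if (climate$noise_sd > 0) {
    eps <- with_seed(seed, {
      innov <- stats::rnorm(length(dates), 0,
                            climate$noise_sd * sqrt(1 - climate$ar1^2))
      e <- numeric(length(dates))
      e[1L] <- stats::rnorm(1L, 0, climate$noise_sd)
      for (t in seq_along(dates)[-1L]) e[t] <- climate$ar1 * e[t - 1L] + innov[t]
      e
    })
    tmean <- tmean + eps
  }
  validate_weather(data.frame(date = dates,
                              tmin = tmean - climate$diurnal_range / 2,
                              tmax = tmean + climate$diurnal_range / 2))
}

#' Design of a synthetic trial network
#'
#' Defaults mirror the structure of the field network the generator emulates:
#' 19 cultivars with between 14 and 260 trials each and per-cultivar GST
#' spans between about 2.2 and 8.2 deg C, with 2 days of observation noise on
#' stage dates.
#'
#' @param n_cultivars number of cultivars.
#' @param trials_range integer range (min, max) of trials per cultivar.
#' @param target_gst_span per-cultivar GST span target in deg C; a length-2
#'   vector draws each cultivar's target uniformly from the range.
#' @param emergence_window day-of-year range for emergence dates.
#' @param years calendar years trials may occur in.
#' @param obs_noise_sd sd (days) of the rounded Gaussian observation noise
#'   added independently to flowering and maturity dates.
#' @param base_mean annual mean temperature of the coolest site (deg C).
#' @param annual_amplitude,diurnal_range,noise_sd,ar1 site climate settings,
#'   see [site_climate()].
#' @param seed design seed.
#' @return object of class \code{"trial_design"} (a list).
#' @export
trial_design <- function(n_cultivars = 19L, trials_range = c(14L, 260L),
                         target_gst_span = c(2.2, 8.2),
                         emergence_window = c(110L, 150L),
                         years = 2001:2005, obs_noise_sd = 2,
                         base_mean = 21, annual_amplitude = 7,
                         diurnal_range = 8, noise_sd = 1.5, ar1 = 0.6,
                         seed = 1L) {
  stopifnot(n_cultivars >= 1L, length(trials_range) %in% 1:2,
            obs_noise_sd >= 0)
  if (length(trials_range) == 1L) trials_range <- rep(trials_range, 2L)
  if (length(target_gst_span) == 1L)
    target_gst_span <- rep(target_gst_span, 2L)
  structure(list(n_cultivars = as.integer(n_cultivars),
                 trials_range = as.integer(trials_range),
                 target_gst_span = target_gst_span,
                 emergence_window = as.integer(emergence_window),
                 years = as.integer(years), obs_noise_sd = obs_noise_sd,
                 base_mean = base_mean, annual_amplitude = annual_amplitude,
                 diurnal_range = diurnal_range, noise_sd = noise_sd,
                 ar1 = ar1, seed = as.integer(seed)),
            class = "trial_design")
}

#' Default true cultivar parameters for synthetic experiments
#'
#' By default the truth is the monotone (no-optimum) growing-degree-day
#' family, so that model-mismatch experiments against optimum-temperature
#' families exercise the mechanism of interest: the default climates place
#' warm-end daily temperatures above the optimum-temperature search region
#' of the fitted families, where a monotone truth keeps accelerating but any
#' optimum-temperature family must slow down. Thermal requirements are
#' scaled to give roughly 85-day flowering and 128-day maturity durations at
#' a reference 26 deg C, with a deterministic per-cultivar jitter of
#' +/- 10%.
#'
#' @param cultivar_ids character vector of cultivar ids.
#' @param model true family, one of [pheno_models()].
#' @param seed seed for the jitter draw.
#' @param dur_flowering,dur_maturity target durations (days) at the
#'   reference temperature.
#' @param ref_temp reference daily mean temperature (deg C).
#' @return named list of [cultivar_params()].
#' @export
default_truth_params <- function(cultivar_ids, model = "gdd",
                                 seed = 1L, dur_flowering = 85,
                                 dur_maturity = 128, ref_temp = 26) {
  model <- match.arg(tolower(model), pheno_models())
  rp <- switch(model,
    gdd = response_params("gdd", Tb = 8),
    exponential = response_params("exponential", Tb = 8, TSEN = 0.25),
    bilinear = response_params("bilinear", Tb = 8, To = 30, Tc = 42),
    beta = response_params("beta", Tb = 8, To = 30, Tc = 42, TSEN = 1.25))
  r_ref <- daily_rate(ref_temp, rp)
  jit <- with_seed(derive_seed(seed, "truth-jitter"),
                   stats::runif(length(cultivar_ids), 0.9, 1.1))
  out <- lapply(seq_along(cultivar_ids), function(i) {
    cultivar_params(cultivar_ids[i], rp,
                    theta_flowering = dur_flowering * r_ref * jit[i],
                    theta_maturity = dur_maturity * r_ref * jit[i])
  })
  stats::setNames(out, cultivar_ids)
}

#' Generate a synthetic multi-cultivar trial set with known truth
#'
#' For each cultivar, sites are spaced in annual mean temperature so that the
#' realized within-cultivar GST span matches the design target (to within
#' 0.5 deg C; the spacing is adjusted iteratively and an error is raised if
#' the target cannot be met). Trials are unique (cultivar, site,
#' year) combinations with emergence dates drawn inside the design window;
#' observed stage dates are simulated under the true model and perturbed by
#' independent rounded Gaussian observation noise.
#'
#' @param design a [trial_design()].
#' @param true_params optional named list of true [cultivar_params()], one
#'   per cultivar; defaults to [default_truth_params()] for
#'   \code{design$n_cultivars} cultivars. When supplied, its names define the
#'   cultivar ids and override \code{design$n_cultivars}.
#' @param seed overrides \code{design$seed}.
#' @return list with \code{trials} (trial data.frame), \code{weather} (named
#'   list of weather data.frames) and \code{truth} (generating parameters,
#'   site climates and seed).
#' @export
generate_trials <- function(design, true_params = NULL, seed = design$seed) {
  stopifnot(inherits(design, "trial_design"))
  if (is.null(true_params)) {
    ids <- sprintf("CV%02d", seq_len(design$n_cultivars))
    true_params <- default_truth_params(ids, seed = seed)
  }
  ids <- names(true_params)
  if (is.null(ids) || anyDuplicated(ids))
    stop_rp("generate_trials: true_params must be a uniquely named list")

  weather <- list()
  climates <- list()
  all_trials <- list()
  for (ci in seq_along(ids)) {
    cid <- ids[ci]
    truth <- true_params[[cid]]
    cfg <- with_seed(derive_seed(seed, paste0("design-", cid)), {
      n_trials <- if (design$trials_range[1L] == design$trials_range[2L])
        design$trials_range[1L]
      else sample(design$trials_range[1L]:design$trials_range[2L], 1L)
      span_target <- if (design$target_gst_span[1L] ==
                         design$target_gst_span[2L])
        design$target_gst_span[1L]
      else stats::runif(1L, design$target_gst_span[1L],
                        design$target_gst_span[2L])
      n_sites <- max(2L, ceiling(n_trials / length(design$years)))
      pairs <- expand.grid(site = seq_len(n_sites), year = design$years)
      pairs <- pairs[order(stats::ave(seq_len(nrow(pairs)), pairs$site,
                               FUN = seq_along), pairs$site), ]
      pairs <- pairs[seq_len(n_trials), , drop = FALSE]
      list(n_trials = n_trials, span_target = span_target,
           n_sites = n_sites, pairs = pairs,
           doy = sample(design$emergence_window[1L]:
                          design$emergence_window[2L], n_trials,
                        replace = TRUE),
           noise_f = stats::rnorm(n_trials, 0, design$obs_noise_sd),
           noise_m = stats::rnorm(n_trials, 0, design$obs_noise_sd))
    })

    span_scale <- cfg$span_target
    done <- FALSE
    for (attempt in 1:8) {
      site_means <- design$base_mean +
        seq(0, span_scale, length.out = cfg$n_sites)
      cl <- lapply(seq_len(cfg$n_sites), function(s) {
        site_climate(sprintf("%s_s%02d", cid, s), site_means[s],
                     annual_amplitude = design$annual_amplitude,
                     diurnal_range = design$diurnal_range,
                     noise_sd = design$noise_sd, ar1 = design$ar1)
      })
      wx <- list()
      trs <- vector("list", cfg$n_trials)
      ok <- TRUE
      for (k in seq_len(cfg$n_trials)) {
        s <- cfg$pairs$site[k]; yr <- cfg$pairs$year[k]
        ref <- sprintf("%s_y%d", cl[[s]]$site_id, yr)
        if (is.null(wx[[ref]])) {
          wx[[ref]] <- generate_weather(
            cl[[s]], yr, seed = derive_seed(seed, ref),
            end_date = as.Date(sprintf("%d-06-30", yr + 1L)))
        }
        emg <- as.Date(sprintf("%d-01-01", yr)) + (cfg$doy[k] - 1L)
        sim <- tryCatch(simulate_stage_dates(wx[[ref]], emg, truth),
                        ricepheno_non_maturing = function(e) NULL)
        if (is.null(sim)) { ok <- FALSE; break }
        obs_f <- max(1L, as.integer(round(sim$flowering + cfg$noise_f[k])))
        obs_m <- max(obs_f + 1L,
                     as.integer(round(sim$maturity + cfg$noise_m[k])))
        trs[[k]] <- data.frame(
          trial_id = sprintf("%s_t%03d", cid, k), cultivar_id = cid,
          site_id = cl[[s]]$site_id, year = yr, emergence_date = emg,
          flowering_dae = obs_f, maturity_dae = obs_m, weather_ref = ref,
          stringsAsFactors = FALSE)
      }
      if (!ok)
        stop_rp("generate_trials: cultivar %s never matures under the design climates; adjust the design or truth parameters",
                cid)
      tr_df <- do.call(rbind, trs)
      gst <- vapply(seq_len(nrow(tr_df)), function(k) {
        compute_gst(wx[[tr_df$weather_ref[k]]], tr_df$emergence_date[k],
                    tr_df$emergence_date[k] + tr_df$maturity_dae[k])
      }, numeric(1))
      realized <- max(gst) - min(gst)
      if (abs(realized - cfg$span_target) <= 0.5) {
        done <- TRUE
        break
      }
      # site spacing and within-site spread add up: adjust additively
      span_scale <- span_scale + (cfg$span_target - realized)
      if (span_scale <= 0.05)
        stop_rp("generate_trials: cultivar %s cannot span the target GST range of %.2f deg C (within-site spread alone is %.2f)",
                cid, cfg$span_target, realized - span_scale)
    }
    if (!done)
      stop_rp("generate_trials: cultivar %s cannot reach the target GST span of %.2f deg C (last realized %.2f)",
              cid, cfg$span_target, realized)
    weather[names(wx)] <- wx
    climates[[cid]] <- cl
    all_trials[[cid]] <- tr_df
  }

  trials <- validate_trials(do.call(rbind, all_trials))
  rownames(trials) <- NULL
  list(trials = trials, weather = weather,
       truth = list(seed = as.integer(seed), design = unclass(design),
                    params = true_params, climates = climates))
}

#' Write a synthetic dataset to disk
#'
#' Emits the canonical file dialects: \code{trials.csv}, one
#' \code{weather/<ref>.csv} per series, the true cultivar parameters as a
#' key-value file and the full generating configuration as
#' \code{truth.yaml}.
#'
#' @param dataset output of [generate_trials()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "weather"), recursive = TRUE,
             showWarnings = FALSE)
  write_trials(dataset$trials, file.path(dir, "trials.csv"),
               header_comment = sprintf("synthetic trials, seed=%d",
                                        dataset$truth$seed))
  for (ref in names(dataset$weather))
    write_weather(dataset$weather[[ref]],
                  file.path(dir, "weather", paste0(ref, ".csv")))
  write_cultivar_params(dataset$truth$params,
                        file.path(dir, "true_params.dcf"))
  truth <- dataset$truth
  truth$params <- lapply(truth$params, function(p) {
    c(list(cultivar_id = p$cultivar_id,
           theta_flowering = p$theta_flowering,
           theta_maturity = p$theta_maturity),
      Filter(Negate(is.null), unclass(p$response)))
  })
  truth$climates <- lapply(truth$climates, function(cl)
    lapply(cl, unclass))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Load a directory of weather files
#'
#' Reads every \code{*.csv} under \code{dir} with [read_weather()], keyed by
#' file name without extension (the \code{weather_ref} convention).
#'
#' @param dir directory of weather csv files.
#' @return named list of weather data.frames.
#' @export
load_weather_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop_rp("load_weather_dir: no csv files in %s", dir)
  out <- lapply(files, read_weather)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}
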