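# Auto-calibration of cultivar parameters.
#
# The fit is two-level. The outer search explores the response-shape
# parameters (Tb, and To/Tc/TSEN where the family uses them) inside bounds;
# the inner step is closed form: given a shape, the thermal requirements to
# flowering and maturity are set to the mean accumulated development units at
# the observed stage dates across the calibration trials. With a single
# calibration trial the inner step reproduces that trial exactly.
#
# Inside the optimizer the stage crossing is interpolated fractionally within
# the crossing day, which makes the sum-of-squared-day-errors objective
# piecewise smooth; reported simulations and metrics always use the integer
# first-crossing rule of simulate_stage_dates().

#' Default bounds and grid resolutions for the shape search
#'
#' Bounds are centred on the cardinal temperatures typical of rice
#' development (base near 8 deg C, optimum near 30, ceiling near 42).
#' @return named list of \code{c(lower, upper)} bounds.
#' @export
default_bounds <- function() {
  list(Tb = c(5, 15), To = c(25, 35), Tc = c(38, 46), TSEN = c(0.05, 3))
}

param_resolution <- c(Tb = 0.1, To = 0.1, Tc = 0.1, TSEN = 0.01)

shape_names <- function(model) {
  switch(model,
         gdd = "Tb",
         exponential = c("Tb", "TSEN"),
         bilinear = c("Tb", "To", "Tc"),
         beta = c("Tb", "To", "Tc", "TSEN"))
}

# Precompute per-trial driving temperatures as a padded matrix.
# Padding uses -99 deg C, which yields zero rate in every family, so padded
# days never advance development.
trial_matrix <- function(trials, weather) {
  trials <- validate_trials(trials)
  miss <- setdiff(unique(trials$weather_ref), names(weather))
  if (length(miss))
    stop_rp("calibration: missing weather series: %s",
            paste(miss, collapse = ", "))
  n <- nrow(trials)
  temps <- vector("list", n)
  nlen <- integer(n)
  for (i in seq_len(n)) {
    tr <- trials[i, ]
    w <- validate_weather(weather[[tr$weather_ref]])
    after <- w[w$date > tr$emergence_date, , drop = FALSE]
    if (nrow(after) < tr$maturity_dae)
      stop_rp("calibration: weather %s covers only %d days after emergence of trial %s (observed maturity at DAE %d)",
              tr$weather_ref, nrow(after), tr$trial_id, tr$maturity_dae)
    temps[[i]] <- (after$tmin + after$tmax) / 2
    nlen[i] <- nrow(after)
  }
  maxlen <- max(nlen)
  tmat <- matrix(-99, nrow = maxlen, ncol = n)
  for (i in seq_len(n)) tmat[seq_len(nlen[i]), i] <- temps[[i]]
  list(tmat = tmat, nlen = nlen,
       obs_f = trials$flowering_dae, obs_m = trials$maturity_dae,
       trial_id = trials$trial_id)
}

# Continuous (fractionally interpolated) first crossing per trial.
cont_crossing <- function(C, R, nlen, theta) {
  n <- ncol(C)
  idx <- .colSums(C < theta, nrow(C), n) + 1L
  crossed <- idx <= nlen
  cont <- rep(NA_real_, n)
  if (any(crossed)) {
    ic <- which(crossed)
    prev <- ifelse(idx[ic] == 1L, 0, C[cbind(pmax(idx[ic] - 1L, 1L), ic)])
    cont[ic] <- (idx[ic] - 1L) + (theta - prev) / R[cbind(idx[ic], ic)]
  }
  list(cont = cont, idx = idx, crossed = crossed)
}

# Build the calibration objective for one model family over a trial matrix.
# Returns a function mapping a full named shape vector to
# list(loss, theta_f, theta_m). Non-maturing candidates receive the penalty
# (span_days - obs_dae)^2 + 1e6 per failed trial/stage; infeasible shapes a
# large constant loss.
make_objective <- function(tm, model) {
  BIG <- 1e12
  force(tm); force(model)
  function(shape) {
    rp <- tryCatch(
      response_params(model, Tb = shape[["Tb"]],
                      To = if ("To" %in% names(shape)) shape[["To"]],
                      Tc = if ("Tc" %in% names(shape)) shape[["Tc"]],
                      TSEN = if ("TSEN" %in% names(shape)) shape[["TSEN"]]),
      error = function(e) NULL)
    if (is.null(rp))
      return(list(loss = BIG, theta_f = NA_real_, theta_m = NA_real_))
    R <- matrix(daily_rate(as.vector(tm$tmat), rp), nrow = nrow(tm$tmat))
    C <- apply(R, 2L, cumsum)
    if (!is.matrix(C)) C <- matrix(C, ncol = ncol(R))
    nc <- ncol(C)
    theta_f <- mean(C[cbind(tm$obs_f, seq_len(nc))])
    theta_m <- mean(C[cbind(tm$obs_m, seq_len(nc))])
    if (!is.finite(theta_f) || !is.finite(theta_m) ||
        theta_f <= 0 || theta_m <= theta_f)
      return(list(loss = BIG, theta_f = theta_f, theta_m = theta_m))
    loss <- 0
    for (stage in c("f", "m")) {
      theta <- if (stage == "f") theta_f else theta_m
      obs <- if (stage == "f") tm$obs_f else tm$obs_m
      cr <- cont_crossing(C, R, tm$nlen, theta)
      ok <- cr$crossed
      loss <- loss + sum((cr$cont[ok] - obs[ok])^2) +
        sum((tm$nlen[!ok] - obs[!ok])^2 + 1e6)
    }
    list(loss = loss, theta_f = theta_f, theta_m = theta_m)
  }
}

#' Auto-calibrate cultivar parameters on a calibration trial set
#'
#' Fits one temperature-response family to one cultivar's calibration trials
#' by minimizing the sum of squared day errors over both stages jointly,
#' \deqn{L = \sum_i (sim.flw_i - obs.flw_i)^2 + (sim.mat_i - obs.mat_i)^2,}
#' returning the parameter set with the least difference between observed and
#' simulated phenology. The outer search over shape parameters is an
#' exhaustive grid at the declared resolution (0.1 deg C for cardinal
#' temperatures, 0.01 for TSEN) when a single parameter is free, and a seeded
#' Latin-hypercube multistart with Nelder-Mead refinement plus an on-grid
#' hill-climbing polish otherwise. Thermal requirements are set by the
#' closed-form inner step (mean accumulated units at the observed stage
#' dates), so they are never free dimensions. The procedure is deterministic
#' given \code{seed}; ties are resolved to the lexicographically smallest
#' shape vector.
#'
#' @param trials calibration trials (validated trial data.frame) of a single
#'   cultivar.
#' @param weather named list of weather data.frames keyed by
#'   \code{weather_ref}.
#' @param model one of [pheno_models()].
#' @param bounds named list of \code{c(lower, upper)} search bounds; see
#'   [default_bounds()].
#' @param fixed named list of shape parameters to pin at given values
#'   (excluded from the search).
#' @param seed integer seed for the multistart draw.
#' @param control optional list: \code{n_starts} (Latin-hypercube points,
#'   default \code{25 * d}), \code{n_refine} (starts refined locally, default
#'   3), \code{nm_maxit} (Nelder-Mead iterations, default \code{200 * d}),
#'   \code{polish_maxit} (grid-polish moves, default 300).
#' @return object of class \code{"pheno_fit"} with components
#'   \code{cultivar_id}, \code{model}, \code{params} ([cultivar_params()]),
#'   \code{objective_value}, \code{converged}, \code{seed}, \code{n_evals},
#'   \code{metrics_flowering}, \code{metrics_maturity} ([fit_metrics()] on
#'   the calibration set), and \code{calibration} (per-trial observed and
#'   simulated DAE).
#' @examples
#' cv <- cultivar_params("demo", response_params("gdd", Tb = 8), 900, 1600)
#' synth <- generate_trials(trial_design(n_cultivars = 1, trials_range = c(8, 8),
#'                                       obs_noise_sd = 0, seed = 7),
#'                          true_params = list(demo = cv))
#' fit <- calibrate_cultivar(synth$trials, synth$weather, "gdd")
#' coef(fit)
#' @export
calibrate_cultivar <- function(trials, weather, model,
                               bounds = default_bounds(), fixed = list(),
                               seed = 1L, control = list()) {
  model <- match.arg(tolower(model), pheno_models())
  trials <- validate_trials(trials)
  if (length(unique(trials$cultivar_id)) != 1L)
    stop_rp("calibrate_cultivar: trials must belong to a single cultivar (got %s)",
            paste(unique(trials$cultivar_id), collapse = ", "))
  cid <- trials$cultivar_id[1L]
  bounds <- utils::modifyList(default_bounds(), bounds)
  tm <- trial_matrix(trials, weather)
  obj <- make_objective(tm, model)
  n_evals <- 0L
  eval_loss <- function(shape) {
    n_evals <<- n_evals + 1L
    obj(shape)$loss
  }

  pn <- shape_names(model)
  if (length(fixed)) {
    bad <- setdiff(names(fixed), pn)
    if (length(bad))
      stop_rp("calibrate_cultivar: fixed parameter(s) %s not used by the %s model",
              paste(bad, collapse = ", "), model)
  }
  free <- setdiff(pn, names(fixed))
  full_shape <- function(p) {
    s <- c(unlist(fixed), p)
    s[pn]
  }
  lo <- vapply(free, function(nm) bounds[[nm]][1L], numeric(1))
  hi <- vapply(free, function(nm) bounds[[nm]][2L], numeric(1))
  res <- param_resolution[free]
  if (any(hi < lo))
    stop_rp("calibrate_cultivar: invalid bounds (upper < lower)")
  snap <- function(p) pmin(hi, pmax(lo, lo + round((p - lo) / res) * res))

  converged <- TRUE
  if (length(free) == 0L) {
    best <- numeric(0)
  } else if (length(free) == 1L) {
    grid <- seq(lo, hi, by = res)
    losses <- vapply(grid, function(v) {
      p <- stats::setNames(v, free)
      eval_loss(full_shape(p))
    }, numeric(1))
    best <- stats::setNames(grid[which.min(losses)], free)
  } else {
    d <- length(free)
    n_starts <- control$n_starts %||% (25L * d)
    n_refine <- control$n_refine %||% 3L
    nm_maxit <- control$nm_maxit %||% (200L * d)
    polish_maxit <- control$polish_maxit %||% 300L
    U <- with_seed(derive_seed(seed, paste0(cid, model)),
                   lhs::randomLHS(n_starts, d))
    starts <- sweep(sweep(U, 2L, hi - lo, "*"), 2L, lo, "+")
    starts <- rbind(starts, (lo + hi) / 2)
    start_loss <- apply(starts, 1L, function(p) {
      eval_loss(full_shape(stats::setNames(p, free)))
    })
    ord <- order(start_loss)
    cand <- list()
    pen_fn <- function(p) {
      if (any(p < lo) || any(p > hi))
        return(1e10 + 1e6 * sum(pmax(lo - p, 0) + pmax(p - hi, 0)))
      eval_loss(full_shape(stats::setNames(p, free)))
    }
    for (k in ord[seq_len(min(n_refine, nrow(starts)))]) {
      opt <- stats::optim(starts[k, ], pen_fn, method = "Nelder-Mead",
                          control = list(maxit = nm_maxit, reltol = 1e-10))
      p <- snap(opt$par)
      # on-grid hill climb: move to the best strictly improving neighbour
      cur_loss <- eval_loss(full_shape(stats::setNames(p, free)))
      moves <- 0L
      repeat {
        nb <- do.call(rbind, lapply(seq_len(d), function(j) {
          rbind(replace(p, j, min(hi[j], p[j] + res[j])),
                replace(p, j, max(lo[j], p[j] - res[j])))
        }))
        nb_loss <- apply(nb, 1L, function(q) {
          eval_loss(full_shape(stats::setNames(q, free)))
        })
        if (min(nb_loss) < cur_loss - 1e-12 && moves < polish_maxit) {
          w <- which.min(nb_loss)
          p <- nb[w, ]
          cur_loss <- nb_loss[w]
          moves <- moves + 1L
        } else break
      }
      if (moves >= polish_maxit) converged <- FALSE
      cand[[length(cand) + 1L]] <- list(p = p, loss = cur_loss)
    }
    losses <- vapply(cand, `[[`, numeric(1), "loss")
    keep <- which(losses <= min(losses) + 1e-9 * max(1, abs(min(losses))))
    pm <- do.call(rbind, lapply(cand[keep], `[[`, "p"))
    lex <- do.call(order, as.data.frame(pm))
    best <- stats::setNames(pm[lex[1L], ], free)
  }

  shape <- full_shape(best)
  final <- obj(shape)
  if (!is.finite(final$loss) || final$loss >= 1e12)
    stop_rp("calibrate_cultivar: no feasible parameter set found within bounds for cultivar %s (%s model)",
            cid, model)
  rp <- response_params(model, Tb = shape[["Tb"]],
                        To = if ("To" %in% names(shape)) shape[["To"]],
                        Tc = if ("Tc" %in% names(shape)) shape[["Tc"]],
                        TSEN = if ("TSEN" %in% names(shape)) shape[["TSEN"]])
  params <- cultivar_params(cid, rp, final$theta_f, final$theta_m)

  # integer first-crossing simulations for reporting
  R <- matrix(daily_rate(as.vector(tm$tmat), rp), nrow = nrow(tm$tmat))
  C <- apply(R, 2L, cumsum)
  if (!is.matrix(C)) C <- matrix(C, ncol = ncol(R))
  sim_f <- .colSums(C < final$theta_f, nrow(C), ncol(C)) + 1L
  sim_m <- .colSums(C < final$theta_m, nrow(C), ncol(C)) + 1L
  calib <- data.frame(trial_id = tm$trial_id,
                      obs_flowering = tm$obs_f, obs_maturity = tm$obs_m,
                      sim_flowering = as.integer(sim_f),
                      sim_maturity = as.integer(sim_m),
                      stringsAsFactors = FALSE)

  structure(list(cultivar_id = cid, model = model, params = params,
                 objective_value = final$loss, converged = converged,
                 seed = as.integer(seed), n_evals = n_evals,
                 metrics_flowering = fit_metrics(calib$obs_flowering,
                                                 calib$sim_flowering),
                 metrics_maturity = fit_metrics(calib$obs_maturity,
                                                calib$sim_maturity),
                 calibration = calib, bounds = bounds, fixed = fixed,
                 objective_fn = obj),
            class = "pheno_fit")
}

#' Apply a calibrated fit to validation trials
#'
#' Pure application of the calibrated parameters: simulates each validation
#' trial with the integer first-crossing rule, without any refitting. Trials
#' whose accumulation never reaches maturity within their weather span are
#' excluded and counted (reported via a message and the
#' \code{"n_non_maturing"} attribute).
#'
#' @param fit a \code{"pheno_fit"} from [calibrate_cultivar()] (or any
#'   [cultivar_params()] object).
#' @param trials validation trials.
#' @param weather named weather list keyed by \code{weather_ref}.
#' @param trials_gst optional output of [assign_delta_gst()]; if supplied, a
#'   \code{delta_gst} column is joined onto the result.
#' @return data.frame \code{trial_id, obs_flowering, obs_maturity,
#'   sim_flowering, sim_maturity[, delta_gst]}, one row per maturing trial.
#' @export
validate_cultivar <- function(fit, trials, weather, trials_gst = NULL) {
  params <- if (inherits(fit, "pheno_fit")) fit$params else fit
  if (!inherits(params, "cultivar_params"))
    stop_rp("validate_cultivar: `fit` must be a pheno_fit or cultivar_params object")
  trials <- validate_trials(trials)
  if (!nrow(trials)) {
    warn_rp("validate_cultivar: empty validation set")
    out <- data.frame(trial_id = character(0), obs_flowering = integer(0),
                      obs_maturity = integer(0), sim_flowering = integer(0),
                      sim_maturity = integer(0))
    attr(out, "n_non_maturing") <- 0L
    return(out)
  }
  rows <- vector("list", nrow(trials))
  n_fail <- 0L
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    sim <- tryCatch(
      simulate_stage_dates(weather[[tr$weather_ref]], tr$emergence_date,
                           params),
      ricepheno_non_maturing = function(e) NULL)
    if (is.null(sim)) {
      n_fail <- n_fail + 1L
      next
    }
    rows[[i]] <- data.frame(trial_id = tr$trial_id,
                            obs_flowering = tr$flowering_dae,
                            obs_maturity = tr$maturity_dae,
                            sim_flowering = sim$flowering,
                            sim_maturity = sim$maturity,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(trial_id = character(0), obs_flowering = integer(0),
                      obs_maturity = integer(0), sim_flowering = integer(0),
                      sim_maturity = integer(0))
  if (n_fail)
    message(sprintf("validate_cultivar: %d non-maturing trial(s) excluded", n_fail))
  if (!is.null(trials_gst)) {
    out$delta_gst <- trials_gst$delta_gst[match(out$trial_id,
                                                trials_gst$trial_id)]
  }
  attr(out, "n_non_maturing") <- n_fail
  rownames(out) <- NULL
  out
}
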