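#' Temperature-response parameter sets
#'
#' Constructs and validates the parameters of one of the four daily
#' temperature-response functions used to drive thermal development:
#'
#' \describe{
#'   \item{\code{"gdd"}}{growing-degree-day response: rate \eqn{= \max(0, T - T_b)}.
#'     Linear above the base temperature, no optimum, no ceiling.}
#'   \item{\code{"exponential"}}{saturating monotone response:
#'     \eqn{1 - \exp(-TSEN (T - T_b))} above \eqn{T_b}, zero below. No optimum;
#'     the asymptotic amplitude is absorbed into the thermal requirements.}
#'   \item{\code{"bilinear"}}{broken-stick response: zero at or below \eqn{T_b}
#'     and at or above \eqn{T_c}, linear rise to 1 at the optimum \eqn{T_o},
#'     linear fall back to zero at the ceiling.}
#'   \item{\code{"beta"}}{Yin-type beta response:
#'     \eqn{[((T-T_b)/(T_o-T_b)) ((T_c-T)/(T_c-T_o))^{(T_c-T_o)/(T_o-T_b)}]^{TSEN}}
#'     inside \eqn{(T_b, T_c)}, zero outside; unimodal with maximum 1 at
#'     \eqn{T_o}.}
#' }
#'
#' The bilinear and beta responses are normalized to a maximum rate of 1 at
#' the optimum; the absolute rate scale is not comparable between model
#' families, so thermal requirements (see [cultivar_params()]) are always
#' model-specific and comparisons across families are made in simulated days.
#'
#' @param model one of \code{"gdd"}, \code{"exponential"}, \code{"bilinear"},
#'   \code{"beta"} (case-insensitive).
#' @param Tb base temperature (deg C); development stops at or below it.
#' @param To optimum temperature (deg C); required for bilinear and beta.
#' @param Tc ceiling temperature (deg C); required for bilinear and beta.
#' @param TSEN dimensionless curvature exponent; required for exponential and
#'   beta, must be positive.
#' @return an object of class \code{"response_params"}.
#' @examples
#' rp <- response_params("bilinear", Tb = 8, To = 30, Tc = 42)
#' daily_rate(c(8, 20, 30, 42), rp)
#' @seealso [daily_rate()], [cultivar_params()]
#' @export
response_params <- function(model, Tb, To = NULL, Tc = NULL, TSEN = NULL) {
  model <- match.arg(tolower(as.character(model)), pheno_models())
  chk_num <- function(x, nm, allow_null = FALSE) {
    if (is.null(x)) {
      if (allow_null) return(NULL)
      stop_rp("response_params: `%s` is required for the %s model", nm, model)
    }
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop_rp("response_params: `%s` must be a single finite number", nm)
    as.numeric(x)
  }
  Tb <- chk_num(Tb, "Tb")
  uses_card <- model %in% c("bilinear", "beta")
  uses_tsen <- model %in% c("exponential", "beta")
  To <- if (uses_card) chk_num(To, "To") else NULL
  Tc <- if (uses_card) chk_num(Tc, "Tc") else NULL
  TSEN <- if (uses_tsen) chk_num(TSEN, "TSEN") else NULL
  if (uses_card && !(Tb < To && To < Tc))
    stop_rp("response_params: need Tb < To < Tc (got Tb=%g, To=%g, Tc=%g)",
            Tb, To, Tc)
  if (uses_tsen && TSEN <= 0)
    stop_rp("response_params: TSEN must be > 0 (got %g)", TSEN)
  structure(list(model = model, Tb = Tb, To = To, Tc = Tc, TSEN = TSEN),
            class = "response_params")
}

#' The four supported phenology model identifiers
#' @return character vector of model ids.
#' @export
pheno_models <- function() c("gdd", "exponential", "bilinear", "beta")

#' Daily thermal development rate
#'
#' Evaluates the temperature-response function at one or more daily mean
#' temperatures. Rates are non-negative and finite; all four families return
#' exactly zero at and below the base temperature, and the bilinear and beta
#' families return exactly zero at and above the ceiling temperature.
#'
#' @param temp numeric vector of daily mean temperatures (deg C); must be
#'   finite.
#' @param params a [response_params()] object.
#' @return numeric vector of development rates, same length as \code{temp}.
#'   Units are degree-days for the GDD family and dimensionless (maximum 1)
#'   for the other three; thermal requirements carry the matching units.
#' @examples
#' daily_rate(20, response_params("gdd", Tb = 8))          # 12 degree-days
#' daily_rate(30, response_params("beta", 8, 30, 42, 1.25)) # 1 (the optimum)
#' @export
daily_rate <- function(temp, params) {
  if (!inherits(params, "response_params"))
    stop_rp("daily_rate: `params` must be a response_params object")
  if (!is.numeric(temp) || anyNA(temp) || any(!is.finite(temp)))
    stop_rp("daily_rate: `temp` must be finite numeric")
  Tb <- params$Tb; To <- params$To; Tc <- params$Tc; TSEN <- params$TSEN
  r <- numeric(length(temp))
  switch(params$model,
    gdd = {
      r <- pmax(0, temp - Tb)
    },
    exponential = {
      i <- temp > Tb
      r[i] <- 1 - exp(-TSEN * (temp[i] - Tb))
    },
    bilinear = {
      up <- temp > Tb & temp <= To
      dn <- temp > To & temp < Tc
      r[up] <- (temp[up] - Tb) / (To - Tb)
      r[dn] <- (Tc - temp[dn]) / (Tc - To)
    },
    beta = {
      i <- temp > Tb & temp < Tc
      cc <- (Tc - To) / (To - Tb)
      base <- ((temp[i] - Tb) / (To - Tb)) * ((Tc - temp[i]) / (Tc - To))^cc
      r[i] <- base^TSEN
    })
  r
}

#' Cultivar parameter set
#'
#' Bundles a temperature response with the cultivar-specific thermal
#' requirements that must be accumulated to reach flowering and maturity.
#' Requirements are in the units of the response family (degree-days for GDD,
#' normalized rate-days otherwise), so they are never comparable across
#' families.
#'
#' @param cultivar_id character identifier.
#' @param response a [response_params()] object.
#' @param theta_flowering cumulative development units to flowering (> 0).
#' @param theta_maturity cumulative development units to maturity
#'   (> \code{theta_flowering}).
#' @return an object of class \code{"cultivar_params"}.
#' @export
cultivar_params <- function(cultivar_id, response, theta_flowering,
                            theta_maturity) {
  if (!inherits(response, "response_params"))
    stop_rp("cultivar_params: `response` must be a response_params object")
  for (nm in c("theta_flowering", "theta_maturity")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_rp("cultivar_params: `%s` must be a single finite number", nm)
  }
  if (!(theta_flowering > 0 && theta_flowering < theta_maturity))
    stop_rp("cultivar_params: need 0 < theta_flowering < theta_maturity (got %g, %g)",
            theta_flowering, theta_maturity)
  structure(list(cultivar_id = as.character(cultivar_id), response = response,
                 theta_flowering = as.numeric(theta_flowering),
                 theta_maturity = as.numeric(theta_maturity)),
            class = "cultivar_params")
}

#' @export
print.response_params <- function(x, ...) {
  flds <- c(Tb = x$Tb, To = x$To, Tc = x$Tc, TSEN = x$TSEN)
  flds <- flds[!vapply(flds, is.null, logical(1))]
  cat(sprintf("<%s response: %s>\n", x$model,
              paste(names(flds), signif(unlist(flds), 6), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.cultivar_params <- function(x, ...) {
  cat(sprintf("<cultivar %s | %s model | theta flowering=%.2f maturity=%.2f>\n",
              x$cultivar_id, x$response$model, x$theta_flowering,
              x$theta_maturity))
  invisible(x)
}
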