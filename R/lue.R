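#' CO2 compensation point in the absence of dark respiration (Gamma*)
#'
#' Arrhenius-type temperature response:
#' Gamma* = exp(c - dHa / (R * (T + 273.15))), with the scaling constant c,
#' activation energy dHa (kJ mol^-1) and molar gas constant R
#' (kJ mol^-1 K^-1) taken from `params`.  At 25 degrees C the default
#' parameterization gives about 42.9 umol mol^-1, consistent with the
#' standard C3 value.
#'
#' @param temp_c Leaf/air temperature in degrees C (vectorised); for site
#'   evaluation this is the growing-season mean temperature G_t.
#' @param params A [lue_params()] object.
#' @return CO2 compensation point, umol mol^-1.
#' @examples
#' gamma_star(25)  # ~42.9
#' @export
gamma_star <- function(temp_c, params = lue_params()) {
  if (any(!is.finite(temp_c))) {
    stop("gamma_star: temperature must be finite")
  }
  if (any(temp_c <= -273.15)) {
    stop("gamma_star: temperature at or below absolute zero")
  }
  exp(params$arrh_c -
        params$arrh_dHa / (params$gas_const_R * (temp_c + 273.15)))
}

#' Intercellular CO2 concentration
#'
#' c_i = c_a * ci_ratio, the conventional constant ratio of intercellular
#' to atmospheric CO2 for C3 canopies (default 0.7, so 400 ppm -> 280).
#'
#' @param c_a Atmospheric CO2 concentration, ppm (vectorised, > 0).
#' @param params A [lue_params()] object.
#' @return Intercellular CO2, umol mol^-1.
#' @export
intercellular_co2 <- function(c_a, params = lue_params()) {
  if (any(!is.finite(c_a)) || any(c_a <= 0)) {
    stop("intercellular_co2: c_a must be finite and > 0")
  }
  c_a * params$ci_ratio
}

#' Rubisco-limited carboxylation term W_i
#'
#' W_i = c_i / (4.5 c_i + 10.5 Gamma*).  Bounded above by 1/4.5 for any
#' Gamma* > 0.
#'
#' @param c_i Intercellular CO2, umol mol^-1 (> 0).
#' @param gamma_star CO2 compensation point, umol mol^-1 (>= 0).
#' @return Dimensionless carboxylation term.
#' @export
rubisco_wi <- function(c_i, gamma_star) {
  if (any(c_i <= 0)) stop("rubisco_wi: c_i must be > 0")
  if (any(gamma_star < 0)) stop("rubisco_wi: gamma_star must be >= 0")
  c_i / (4.5 * c_i + 10.5 * gamma_star)
}

#' Net CO2 uptake efficiency A
#'
#' A = (1 - Gamma*/c_i) * W_i: carboxylation discounted by the
#' photorespiratory cost.  A is zero exactly at the compensation point
#' (c_i = Gamma*) and can be negative below it (extreme cold or very low
#' CO2); the value is returned as-is and callers flag/clamp downstream.
#'
#' @param c_i Intercellular CO2, umol mol^-1 (> 0).
#' @param gamma_star CO2 compensation point, umol mol^-1.
#' @return Dimensionless net uptake efficiency.
#' @export
net_uptake <- function(c_i, gamma_star) {
  (1 - gamma_star / c_i) * rubisco_wi(c_i, gamma_star)
}

#' Photosynthetic conversion efficiency
#'
#' eps_c = A * beta * alpha_leaf: the rate at which absorbed solar energy is
#' converted into plant tissue, from the net uptake efficiency, the
#' fraction of absorbed quanta reaching PSII and the leaf absorptance.
#'
#' @param a_net Net uptake efficiency from [net_uptake()].
#' @param params A [lue_params()] object.
#' @return Dimensionless conversion efficiency.
#' @export
conversion_efficiency <- function(a_net, params = lue_params()) {
  a_net * params$beta * params$alpha_leaf
}

#' Theoretical maximum total NPP
#'
#' Canonical form ("script"): usable energy over the season
#' E = G_srad * G_d * par_frac * eps_i * eps_c / 1000  (MJ m^-2 yr^-1,
#' from kJ m^-2 day^-1 input), converted to dry biomass by the specific
#' energy K (MJ kg^-1) and to field units by 10 (kg m^-2 -> Mg ha^-1):
#' tNpp_tmax = E / K * 10.  An empty growing season yields 0.
#'
#' `formula = "equation"` exposes, for comparison only, the compact
#' published product G_srad * eps_c * eps_i * K, which omits the day count
#' and PAR fraction and re-applies eps_i; it is not dimensionally
#' consistent with Mg ha^-1 yr^-1 and is not used by [evaluate_site()].
#'
#' @param gs A [derive_growing_season()] result.
#' @param eps_c Conversion efficiency from [conversion_efficiency()].
#' @param params A [lue_params()] object.
#' @param formula `"script"` (canonical, default) or `"equation"`.
#' @return Theoretical maximum total NPP, Mg ha^-1 yr^-1.
#' @export
tnpp_tmax <- function(gs, eps_c, params = lue_params(),
                      formula = c("script", "equation")) {
  stopifnot(inherits(gs, "growing_season"))
  formula <- match.arg(formula)
  if (gs$g_days == 0L) return(0)
  if (is.na(gs$g_srad)) {
    stop("tnpp_tmax: growing season has days but undefined mean radiation")
  }
  if (formula == "equation") {
    return(gs$g_srad * eps_c * params$eps_i * params$spec_energy_K)
  }
  energy_mj <- gs$g_srad * gs$g_days * params$par_frac * params$eps_i *
    eps_c / 1000
  energy_mj / params$spec_energy_K * 10
}

#' Ecosystem Fit
#'
#' eFit = 100 * tNpp_obs / tNpp_tmax: the percent of a site's theoretical
#' productive capacity realized in the field.  Values above 100 are
#' permitted but flagged with a warning (observed productivity exceeding
#' the modeled maximum signals input or assumption problems).
#'
#' @param tnpp_obs Observed total NPP, Mg ha^-1 yr^-1.
#' @param tnpp_tmax Theoretical maximum total NPP, Mg ha^-1 yr^-1 (not 0).
#' @param ratio If `TRUE` return the plain ratio instead of percent.
#' @return Ecosystem Fit in percent (or as a ratio).
#' @examples
#' ecosystem_fit(22, 72.96)  # ~30.2
#' @export
ecosystem_fit <- function(tnpp_obs, tnpp_tmax, ratio = FALSE) {
  if (any(tnpp_tmax == 0)) {
    stop("ecosystem_fit: tnpp_tmax is 0; eFit undefined")
  }
  r <- tnpp_obs / tnpp_tmax
  if (any(r > 1, na.rm = TRUE)) {
    warning("ecosystem_fit: observed tNpp exceeds theoretical maximum (",
            sum(r > 1, na.rm = TRUE), " value(s) > 100%)")
  }
  if (ratio) r else 100 * r
}

#' Evaluate the full model chain for one site
#'
#' Chains growing-season derivation, CO2 lookup for the site's observation
#' year, the compensation point at the growing-season mean temperature,
#' intercellular CO2, net uptake, conversion efficiency, theoretical
#' maximum NPP and (when an observation is present) Ecosystem Fit.  All
#' intermediates are retained.  Degenerate situations never raise: an
#' empty season gives tnpp_tmax = 0 and undefined eFit; a non-positive net
#' uptake clamps tnpp_tmax to 0; each condition adds a flag.
#'
#' @param site One site record: a list or one-row data.frame with
#'   `site_id`, optional `year` and `tnpp_obs`.
#' @param climate The site's [monthly_climate()].
#' @param co2 A [co2_table()] (default: packaged record).
#' @param params A [lue_params()] object.
#' @param warm_threshold,strict Passed to [derive_growing_season()].
#' @param fallback_ppm Optional CO2 fallback, see [co2_for_year()].
#' @return One-row data.frame: site_id, g_days, g_temp, g_srad, c_a, c_i,
#'   gamma_star, w_i, a_net, eps_c, tnpp_tmax, efit, flags
#'   (semicolon-separated; empty when clean).
#' @export
evaluate_site <- function(site, climate, co2 = default_co2_table(),
                          params = lue_params(), warm_threshold = 0,
                          strict = FALSE, fallback_ppm = NULL) {
  flags <- character(0)
  gs <- derive_growing_season(climate, warm_threshold, strict)
  if (!gs$complete) flags <- c(flags, "incomplete_climate")

  yr <- if (!is.null(site$year)) site$year else NA
  c_a <- tryCatch(co2_for_year(yr, co2, fallback_ppm),
                  error = function(e) NA_real_)
  if (is.na(c_a)) flags <- c(flags, "co2_unresolved")

  g <- w <- a <- ec <- c_i <- NA_real_
  tmax <- NA_real_
  if (gs$g_days == 0L) {
    tmax <- 0
    flags <- c(flags, "empty_season")
  } else if (!is.na(c_a) && !is.na(gs$g_temp)) {
    g <- gamma_star(gs$g_temp, params)
    c_i <- intercellular_co2(c_a, params)
    w <- rubisco_wi(c_i, g)
    a <- net_uptake(c_i, g)
    ec <- conversion_efficiency(a, params)
    if (a <= 0) {
      tmax <- 0
      flags <- c(flags, "a_nonpositive")
    } else if (is.na(gs$g_srad)) {
      flags <- c(flags, "no_radiation")
    } else {
      tmax <- tnpp_tmax(gs, ec, params)
    }
  }

  obs <- if (!is.null(site$tnpp_obs)) as.numeric(site$tnpp_obs) else NA_real_
  efit <- NA_real_
  if (!is.na(obs) && !is.na(tmax)) {
    if (tmax == 0) {
      flags <- c(flags, "efit_undefined")
    } else {
      efit <- withCallingHandlers(
        ecosystem_fit(obs, tmax),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (efit > 100) flags <- c(flags, "efit_gt_100")
    }
  }

  data.frame(
    site_id = as.character(site$site_id), g_days = gs$g_days,
    g_temp = gs$g_temp, g_srad = gs$g_srad, c_a = c_a, c_i = c_i,
    gamma_star = g, w_i = w, a_net = a, eps_c = ec, tnpp_tmax = tmax,
    efit = efit, flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Evaluate many sites, never aborting on one bad site
#'
#' @param sites Data.frame of site records (see [read_sites()]).
#' @param climates Named list mapping site_id to [monthly_climate()], as
#'   produced by [read_climate_table()] or [extract_monthly()].
#' @param ... Passed to [evaluate_site()].
#' @return Data.frame with one row per site (same order as `sites`);
#'   per-site failures are recorded in the `flags` column as
#'   `error:<message>` with all numeric fields `NA`.
#' @export
evaluate_sites <- function(sites, climates, ...) {
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    id <- as.character(sites$site_id[i])
    rows[[i]] <- tryCatch({
      cl <- climates[[id]]
      if (is.null(cl)) stop("no climate for site ", id)
      evaluate_site(as.list(sites[i, , drop = FALSE]), cl, ...)
    }, error = function(e) {
      data.frame(site_id = id, g_days = NA_integer_, g_temp = NA_real_,
                 g_srad = NA_real_, c_a = NA_real_, c_i = NA_real_,
                 gamma_star = NA_real_, w_i = NA_real_, a_net = NA_real_,
                 eps_c = NA_real_, tnpp_tmax = NA_real_, efit = NA_real_,
                 flags = paste0("error:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
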