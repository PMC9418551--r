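#' Physiological parameters for the light-use-efficiency model
#'
#' Bundles every constant entering the computation of the CO2 compensation
#' point, the rubisco-limited uptake term, the photosynthetic conversion
#' efficiency and the theoretical maximum productivity.  Defaults follow the
#' standard C3 parameterization used for this model family (Bernacchi-type
#' Arrhenius response of the compensation point; Monteith-style radiation
#' conversion).
#'
#' @param gas_const_R Molar gas constant, kJ mol^-1 K^-1.
#' @param spec_energy_K Specific energy of plant dry biomass, MJ kg^-1.
#'   Default 18.2; an alternative literature value of 18.4 can be supplied
#'   here if desired.
#' @param arrh_c Dimensionless scaling constant of the Arrhenius expression
#'   for the CO2 compensation point.
#' @param arrh_dHa Activation energy of the compensation-point response,
#'   kJ mol^-1.
#' @param beta Fraction of absorbed quanta reaching Photosystem II.
#' @param eps_i Canopy interception efficiency: fraction of incoming PAR
#'   absorbed by the canopy during active growth.
#' @param alpha_leaf Leaf absorptance.
#' @param par_frac Photosynthetically active fraction of total solar
#'   radiation.
#' @param ci_ratio Ratio of intercellular to atmospheric CO2 concentration.
#'
#' @return An object of class `lue_params`: a named list of validated
#'   numeric scalars.
#' @examples
#' p <- lue_params()
#' p$spec_energy_K     # 18.2
#' lue_params(ci_ratio = 0.8)
#' @export
lue_params <- function(gas_const_R = 0.008314,
                       spec_energy_K = 18.2,
                       arrh_c = 19.02,
                       arrh_dHa = 37.83,
                       beta = 0.45,
                       eps_i = 0.90,
                       alpha_leaf = 0.90,
                       par_frac = 0.45,
                       ci_ratio = 0.70) {
  p <- list(
    gas_const_R = gas_const_R, spec_energy_K = spec_energy_K,
    arrh_c = arrh_c, arrh_dHa = arrh_dHa, beta = beta, eps_i = eps_i,
    alpha_leaf = alpha_leaf, par_frac = par_frac, ci_ratio = ci_ratio
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("lue_params: '", nm, "' must be a finite numeric scalar")
    }
  }
  # fractions and efficiencies live in (0, 1]
  for (nm in c("beta", "eps_i", "alpha_leaf", "par_frac", "ci_ratio")) {
    if (p[[nm]] <= 0 || p[[nm]] > 1) {
      stop("lue_params: '", nm, "' must be in (0, 1], got ", p[[nm]])
    }
  }
  if (p$spec_energy_K <= 0) stop("lue_params: 'spec_energy_K' must be > 0")
  if (p$arrh_dHa <= 0) stop("lue_params: 'arrh_dHa' must be > 0")
  if (p$gas_const_R <= 0) stop("lue_params: 'gas_const_R' must be > 0")
  structure(p, class = "lue_params")
}

#' @export
print.lue_params <- function(x, ...) {
  cat("Light-use-efficiency model parameters:\n")
  units <- c(
    gas_const_R = "kJ mol^-1 K^-1", spec_energy_K = "MJ kg^-1",
    arrh_c = "-", arrh_dHa = "kJ mol^-1", beta = "-", eps_i = "-",
    alpha_leaf = "-", par_frac = "-", ci_ratio = "-"
  )
  for (nm in names(x)) {
    cat(sprintf("  %-14s %10g  [%s]\n", nm, x[[nm]], units[[nm]]))
  }
  invisible(x)
}

#' Calendar days per month (non-leap year)
#'
#' The growing-season day count credits each warm month with its full
#' calendar length; a fixed 365-day (non-leap) calendar is used throughout.
#'
#' @return Integer vector of length 12, January first:
#'   31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31.
#' @examples
#' month_day_table()[2]   # February: 28
#' sum(month_day_table()) # 365
#' @export
month_day_table <- function() {
  c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
}
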