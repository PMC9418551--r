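#' Climate-zone template for synthetic data
#'
#' Describes one synthetic climate zone with a sinusoidal seasonal cycle
#' (July peak, northern convention; only the set of warm months matters
#' downstream, so the phase convention is harmless).  Observed productivity
#' is generated as a stated fraction of the zone's analytic theoretical
#' maximum, with multiplicative noise.
#'
#' @param name Zone label (used as the synthetic climate_zone).
#' @param t_mean,t_amp Annual mean and seasonal amplitude of monthly mean
#'   temperature, degrees C.
#' @param srad_mean,srad_amp Annual mean and seasonal amplitude of monthly
#'   mean daily solar radiation, kJ m^-2 day^-1.
#' @param obs_fraction Mean of tnpp_obs / tnpp_tmax for the zone, in
#'   (0, 1.5].
#' @param lat,lon Nominal zone center used to place synthetic sites.
#' @return A `zone_template` list.
#' @export
zone_template <- function(name, t_mean, t_amp, srad_mean, srad_amp,
                          obs_fraction = 0.3, lat = 45, lon = 0) {
  if (obs_fraction <= 0 || obs_fraction > 1.5) {
    stop("zone_template: obs_fraction must be in (0, 1.5]")
  }
  if (srad_mean < srad_amp) {
    stop("zone_template: srad_amp may not exceed srad_mean (negative radiation)")
  }
  structure(list(name = name, t_mean = t_mean, t_amp = t_amp,
                 srad_mean = srad_mean, srad_amp = srad_amp,
                 obs_fraction = obs_fraction, lat = lat, lon = lon),
            class = "zone_template")
}

#' Generate a monthly climate from a zone template
#'
#' Monthly means follow T_m = t_mean + t_amp * cos(2 pi (m - 7) / 12) and
#' the analogous series for radiation, plus optional seeded Gaussian
#' jitter.  With zero jitter the exact growing season is computable
#' analytically from the template.
#'
#' @param zone A [zone_template()].
#' @param seed Integer seed for the jitter stream.
#' @param jitter_sd_temp,jitter_sd_srad Standard deviations of the
#'   per-month Gaussian jitter (default 0: deterministic climate).
#' @return A [monthly_climate()].
#' @export
make_climate <- function(zone, seed = 1L, jitter_sd_temp = 0,
                         jitter_sd_srad = 0) {
  stopifnot(inherits(zone, "zone_template"))
  m <- 1:12
  shape <- cos(2 * pi * (m - 7) / 12)
  temp <- zone$t_mean + zone$t_amp * shape
  srad <- zone$srad_mean + zone$srad_amp * shape
  if (jitter_sd_temp > 0 || jitter_sd_srad > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    temp <- temp + stats::rnorm(12, 0, jitter_sd_temp)
    srad <- pmax(0, srad + stats::rnorm(12, 0, jitter_sd_srad))
  }
  monthly_climate(temp, srad)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a synthetic 12-month raster stack
#'
#' Writes 12 georeferenced single-band ESRI ASCII grids with prescribed
#' cell values so extraction answers are closed-form.  Field types:
#' `constant` (every cell = `value` + `month_offsets[m]`), `latgrad`
#' (cell value = latitude of the cell center + `month_offsets[m]`),
#' `checkerboard` (alternating `value`/NoData holes), or `fun`
#' (`value_fun(lon, lat, month)` evaluated at cell centers).
#'
#' @param out_dir Writable directory for the 12 files.
#' @param prefix File name prefix; files are `<prefix>_01.asc` ...
#'   `<prefix>_12.asc`.
#' @param type One of `"constant"`, `"latgrad"`, `"checkerboard"`, `"fun"`.
#' @param value Base cell value (constant/checkerboard fields).
#' @param value_fun Function of `(lon, lat, month)` for `type = "fun"`.
#' @param month_offsets Numeric length-12 additive offsets (default all 0).
#' @param xll,yll,cellsize,ncols,nrows Grid definition in decimal degrees.
#' @return Character vector of the 12 file paths, month order.
#' @export
make_raster_stack <- function(out_dir, prefix = "temp",
                              type = c("constant", "latgrad",
                                       "checkerboard", "fun"),
                              value = 10, value_fun = NULL,
                              month_offsets = rep(0, 12),
                              xll = 0, yll = 40, cellsize = 0.5,
                              ncols = 10, nrows = 10) {
  type <- match.arg(type)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("make_raster_stack: cannot create directory: ", out_dir)
  }
  lon <- xll + (seq_len(ncols) - 0.5) * cellsize
  lat <- yll + (nrows - seq_len(nrows) + 0.5) * cellsize
  paths <- character(12)
  for (mo in 1:12) {
    vals <- switch(type,
      constant = matrix(value + month_offsets[mo], nrows, ncols),
      latgrad = matrix(lat, nrows, ncols) + month_offsets[mo],
      checkerboard = {
        m <- outer(seq_len(nrows), seq_len(ncols),
                   function(i, j) ifelse((i + j) %% 2 == 0,
                                         value + month_offsets[mo], NA_real_))
        m
      },
      fun = {
        if (is.null(value_fun)) stop("make_raster_stack: value_fun required")
        outer(seq_len(nrows), seq_len(ncols),
              function(i, j) value_fun(lon[j], lat[i], mo))
      })
    g <- ascii_grid(vals, xll, yll, cellsize)
    paths[mo] <- file.path(out_dir, sprintf("%s_%02d.asc", prefix, mo))
    write_ascii_grid(g, paths[mo])
  }
  paths
}

#' Specification of a synthetic multi-zone site dataset
#'
#' @param zones List of [zone_template()]s.
#' @param n_sites Total number of sites (>= 1), dealt round-robin across
#'   zones.
#' @param noise_sd Relative (multiplicative) standard deviation of
#'   observation noise on tnpp_obs (default 0.1; 0 gives a noiseless
#'   dataset whose pipeline output equals the truth table exactly).
#' @param obs_spread Relative spread of each site's target obs fraction
#'   around the zone's `obs_fraction` (default 0: all sites at the zone
#'   mean).
#' @param jitter_sd_temp,jitter_sd_srad Per-month climate jitter passed to
#'   [make_climate()].
#' @param year_range Calendar years assigned cyclically to sites; must be
#'   covered by the CO2 table used downstream.
#' @param seed Master seed; all site-level randomness derives from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(zones, n_sites = 30, noise_sd = 0.1,
                       obs_spread = 0, jitter_sd_temp = 0,
                       jitter_sd_srad = 0, year_range = 1981:2011,
                       seed = 1L) {
  if (inherits(zones, "zone_template")) zones <- list(zones)
  stopifnot(length(zones) >= 1, n_sites >= 1)
  structure(list(zones = zones, n_sites = as.integer(n_sites),
                 noise_sd = noise_sd, obs_spread = obs_spread,
                 jitter_sd_temp = jitter_sd_temp,
                 jitter_sd_srad = jitter_sd_srad,
                 year_range = as.integer(year_range),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Straight-line transcription of the model chain used ONLY to build the
# generator's truth table; deliberately independent of evaluate_site().
.truth_chain <- function(temp, srad, c_a, p = lue_params()) {
  md <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  warm <- !is.na(temp) & temp >= 0
  g_days <- sum(md[warm])
  if (g_days == 0) {
    return(list(g_days = 0, g_temp = NA_real_, g_srad = NA_real_,
                tnpp_tmax = 0))
  }
  g_temp <- mean(temp[warm])
  g_srad <- mean(srad[warm], na.rm = TRUE)
  gamma <- exp(p$arrh_c - p$arrh_dHa / (p$gas_const_R * (g_temp + 273.15)))
  ci <- c_a * p$ci_ratio
  wi <- ci / (4.5 * ci + 10.5 * gamma)
  a <- (1 - gamma / ci) * wi
  ec <- a * p$beta * p$alpha_leaf
  tn <- g_srad * g_days * p$par_frac * p$eps_i * ec / 1000 /
    p$spec_energy_K * 10
  list(g_days = g_days, g_temp = g_temp, g_srad = g_srad,
       tnpp_tmax = max(0, tn))
}

#' Generate a synthetic site dataset with an analytic truth table
#'
#' Emits a site table, a per-site monthly climate table and a truth table
#' holding each site's analytic growing season, theoretical maximum NPP
#' and expected Ecosystem Fit, for parameter-recovery and round-trip
#' tests.  Observed tNpp is drawn as
#' fraction * tnpp_tmax * (1 + N(0, noise_sd)); with `noise_sd = 0` the
#' pipeline-recovered eFit equals the truth-table eFit exactly.  Fully
#' deterministic given the spec's seed; each site uses a sub-stream keyed
#' by its index, so subsetting sites does not change their draws.
#'
#' @param spec A [synth_spec()].
#' @param co2 A [co2_table()] used to assign c_a (default packaged
#'   record).
#' @param params A [lue_params()].
#' @param dir Optional directory; when given, `sites.csv`, `climate.csv`,
#'   `truth.csv` and `co2.csv` are written there.
#' @return List with data.frames `sites`, `climate`, `truth`, and the
#'   `co2` table used.
#' @export
make_dataset <- function(spec, co2 = default_co2_table(),
                         params = lue_params(), dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  nz <- length(spec$zones)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  sites <- climate <- truth <- vector("list", spec$n_sites)
  for (i in seq_len(spec$n_sites)) {
    zone <- spec$zones[[((i - 1) %% nz) + 1]]
    site_seed <- (spec$seed * 1000L + i) %% .Machine$integer.max
    cl <- make_climate(zone, seed = site_seed,
                       jitter_sd_temp = spec$jitter_sd_temp,
                       jitter_sd_srad = spec$jitter_sd_srad)
    year <- spec$year_range[((i - 1) %% length(spec$year_range)) + 1]
    c_a <- co2_for_year(year, co2)
    tr <- .truth_chain(cl$temp, cl$srad, c_a, params)

    set.seed((site_seed + 500L) %% .Machine$integer.max)
    frac <- zone$obs_fraction *
      (1 + if (spec$obs_spread > 0) stats::rnorm(1, 0, spec$obs_spread) else 0)
    frac <- min(max(frac, 1e-3), 1.5)
    noise <- if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0
    obs <- max(frac * tr$tnpp_tmax * (1 + noise), 1e-6)

    id <- sprintf("S%03d", i)
    # small deterministic scatter around the zone center keeps sites distinct
    sites[[i]] <- data.frame(
      site_id = id, lon = zone$lon + 0.01 * i, lat = zone$lat,
      year = year, tnpp_obs = obs, climate_zone = zone$name,
      phenology = if (i %% 2 == 0) "evergreen" else "deciduous",
      stringsAsFactors = FALSE
    )
    cli <- as.list(c(cl$temp, cl$srad))
    names(cli) <- c(sprintf("temp_%02d", 1:12), sprintf("srad_%02d", 1:12))
    climate[[i]] <- data.frame(site_id = id, cli, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      site_id = id, g_days = tr$g_days, g_temp = tr$g_temp,
      g_srad = tr$g_srad, c_a = c_a, tnpp_tmax = tr$tnpp_tmax,
      efit = if (tr$tnpp_tmax > 0) 100 * obs / tr$tnpp_tmax else NA_real_,
      obs_fraction = frac, stringsAsFactors = FALSE
    )
  }
  out <- list(sites = do.call(rbind, sites),
              climate = do.call(rbind, climate),
              truth = do.call(rbind, truth),
              co2 = co2)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(out$sites, file.path(dir, "sites.csv"),
                     row.names = FALSE)
    utils::write.csv(out$climate, file.path(dir, "climate.csv"),
                     row.names = FALSE)
    utils::write.csv(out$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(co2)[c("year", "ppm")]),
                     file.path(dir, "co2.csv"), row.names = FALSE)
  }
  out
}
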