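#' Monthly climate record for one site
#'
#' Twelve monthly mean temperatures and twelve monthly mean daily solar
#' radiation values, January-first ordering, plus the fixed non-leap month
#' lengths.  Missing months are represented as `NA` and tracked; they are
#' never imputed.
#'
#' @param temp Numeric vector of 12 monthly mean temperatures, degrees C.
#' @param srad Numeric vector of 12 monthly mean daily solar radiation
#'   values, kJ m^-2 day^-1.  Non-missing values must be >= 0.
#' @return An object of class `monthly_climate` with components `temp`,
#'   `srad` and `month_days`.
#' @examples
#' mc <- monthly_climate(rep(20, 12), rep(15000, 12))
#' @export
monthly_climate <- function(temp, srad) {
  temp <- as.numeric(temp)
  srad <- as.numeric(srad)
  if (length(temp) != 12L || length(srad) != 12L) {
    stop("monthly_climate: 'temp' and 'srad' must each have exactly 12 entries")
  }
  if (any(srad < 0, na.rm = TRUE)) {
    stop("monthly_climate: negative solar radiation value(s): ",
         paste(which(!is.na(srad) & srad < 0), collapse = ", "))
  }
  structure(list(temp = temp, srad = srad, month_days = month_day_table()),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat("Monthly climate (Jan..Dec):\n")
  cat("  temp [degC]:         ", paste(format(x$temp, digits = 4), collapse = " "), "\n")
  cat("  srad [kJ/m^2/day]:   ", paste(format(x$srad, digits = 5), collapse = " "), "\n")
  invisible(x)
}

#' Read a site table
#'
#' Reads a delimited site table with one row per forest plot.  Required
#' columns: `site_id`, `lon`, `lat`.  Optional columns: `year`, `tnpp_obs`
#' (observed total NPP, Mg ha^-1 yr^-1), `climate_zone`, `phenology`.
#' Rows whose coordinates are missing or outside WGS84 bounds are dropped
#' with a row-level warning; non-positive `tnpp_obs` values are set to `NA`
#' with a warning.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field delimiter (default comma).
#' @return A data.frame of site records, one row per accepted site.
#' @export
read_sites <- function(path, sep = ",") {
  if (!file.exists(path)) stop("read_sites: file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("site_id", "lon", "lat")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("read_sites: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) {
    stop("read_sites: duplicate site_id value(s): ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  }
  df$lon <- suppressWarnings(as.numeric(df$lon))
  df$lat <- suppressWarnings(as.numeric(df$lat))
  bad <- is.na(df$lon) | is.na(df$lat) |
    df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90
  if (any(bad)) {
    warning("read_sites: dropped ", sum(bad), " row(s) with invalid coordinates: ",
            paste(df$site_id[bad], collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  for (opt in c("year", "tnpp_obs")) {
    if (opt %in% names(df)) df[[opt]] <- suppressWarnings(as.numeric(df[[opt]]))
  }
  if ("tnpp_obs" %in% names(df)) {
    nonpos <- !is.na(df$tnpp_obs) & df$tnpp_obs <= 0
    if (any(nonpos)) {
      warning("read_sites: non-positive tnpp_obs set to NA for site(s): ",
              paste(df$site_id[nonpos], collapse = ", "))
      df$tnpp_obs[nonpos] <- NA_real_
    }
  }
  rownames(df) <- NULL
  df
}

#' Read a per-site monthly climate table
#'
#' Tabular alternative to raster extraction.  Expects columns `site_id`,
#' `temp_01`..`temp_12` and `srad_01`..`srad_12`; blank cells become missing
#' months.  Units are taken verbatim as degrees C and kJ m^-2 day^-1.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field delimiter (default comma).
#' @return A named list mapping `site_id` to [monthly_climate()] objects.
#' @export
read_climate_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("read_climate_table: file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  tcols <- sprintf("temp_%02d", 1:12)
  scols <- sprintf("srad_%02d", 1:12)
  missing_cols <- setdiff(c(tcols, scols), names(df))
  if (length(missing_cols) > 0) {
    stop("read_climate_table: missing climate column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"site_id" %in% names(df)) {
    stop("read_climate_table: missing required column: site_id")
  }
  out <- vector("list", nrow(df))
  names(out) <- as.character(df$site_id)
  for (i in seq_len(nrow(df))) {
    temp <- suppressWarnings(as.numeric(df[i, tcols]))
    srad <- suppressWarnings(as.numeric(df[i, scols]))
    out[[i]] <- monthly_climate(temp, srad)
  }
  out
}

#' Construct an annual CO2 table
#'
#' @param year Integer vector of calendar years, strictly increasing.
#' @param ppm Annual mean atmospheric CO2 concentrations, ppm; must lie in
#'   (150, 1000).
#' @return An object of class `co2_table` (a data.frame with columns
#'   `year` and `ppm`).
#' @export
co2_table <- function(year, ppm) {
  year <- as.integer(year)
  ppm <- as.numeric(ppm)
  if (length(year) != length(ppm) || length(year) == 0) {
    stop("co2_table: 'year' and 'ppm' must be equal-length, non-empty")
  }
  if (any(diff(year) <= 0)) stop("co2_table: years must be strictly increasing")
  if (any(!is.finite(ppm)) || any(ppm <= 150) || any(ppm >= 1000)) {
    stop("co2_table: ppm values must lie in (150, 1000)")
  }
  structure(data.frame(year = year, ppm = ppm),
            class = c("co2_table", "data.frame"))
}

#' Read an annual CO2 table from a two-column delimited file
#'
#' @param path File with header columns `year` and `ppm`.
#' @param sep Field delimiter (default comma).
#' @return A [co2_table()].
#' @export
read_co2_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("read_co2_table: file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("year", "ppm") %in% names(df))) {
    stop("read_co2_table: file must have 'year' and 'ppm' columns")
  }
  co2_table(df$year, df$ppm)
}

#' Packaged annual mean atmospheric CO2 (Mauna Loa style), 1959-2022
#'
#' Convenience table of annual mean atmospheric CO2 concentrations as
#' reported for the Mauna Loa Observatory record, shipped as a plain-text
#' data file.  Use [read_co2_table()] to load site- or source-specific
#' tables instead.
#'
#' @return A [co2_table()] covering 1959-2022.
#' @export
default_co2_table <- function() {
  path <- system.file("extdata", "co2_annual_maunaloa.csv", package = "efitr")
  if (!nzchar(path)) stop("default_co2_table: packaged CO2 table not found")
  read_co2_table(path)
}

#' Resolve atmospheric CO2 for a calendar year
#'
#' Returns the exact-year annual mean if the year is present in the table;
#' otherwise the fallback concentration if one is supplied.  No
#' interpolation between years is performed.
#'
#' @param year Calendar year (integer).
#' @param table A [co2_table()]; defaults to the packaged record.
#' @param fallback_ppm Optional constant concentration used when `year` is
#'   absent from the table (the model's conventional standard is 400 ppm,
#'   but it is applied only when explicitly supplied here).
#' @return Atmospheric CO2 concentration, ppm.
#' @examples
#' co2_for_year(2000)                      # packaged record
#' co2_for_year(1700, fallback_ppm = 400)  # 400
#' @export
co2_for_year <- function(year, table = default_co2_table(),
                         fallback_ppm = NULL) {
  if (length(year) != 1L || is.na(year)) {
    if (!is.null(fallback_ppm)) return(as.numeric(fallback_ppm))
    stop("co2_for_year: year is missing and no fallback_ppm supplied")
  }
  hit <- match(as.integer(year), table$year)
  if (!is.na(hit)) return(table$ppm[hit])
  if (!is.null(fallback_ppm)) return(as.numeric(fallback_ppm))
  stop("co2_for_year: year ", year,
       " not in CO2 table and no fallback_ppm supplied")
}
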