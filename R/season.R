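#' Derive the growing season from monthly climate
#'
#' The growing season is the set of months whose mean temperature meets the
#' warmth criterion (default: at or above 0 degrees C).  Its length G_d is
#' the sum of those months' calendar days (non-leap year), and G_t / G_srad
#' are the unweighted means of temperature and daily solar radiation over
#' the included months -- not day-weighted, mirroring a row-mean over
#' monthly columns.
#'
#' A month with missing temperature is never included.  A warm month with
#' missing radiation still counts toward G_d but is excluded from the
#' G_srad mean; any missing value marks the result incomplete.  An empty
#' season is a valid result: G_d = 0 and G_t / G_srad undefined (`NA`).
#'
#' @param climate A [monthly_climate()] object.
#' @param warm_threshold Warmth criterion in degrees C (default 0).
#' @param strict If `TRUE`, require temperature strictly above the
#'   threshold; the default `FALSE` retains exactly-zero months.
#' @return An object of class `growing_season` with fields `g_days`,
#'   `g_temp`, `g_srad`, `months_used` (integer month indices) and
#'   `complete`.
#' @examples
#' mc <- monthly_climate(c(rep(-5, 3), rep(10, 7), rep(-5, 2)),
#'                       rep(15000, 12))
#' derive_growing_season(mc)$g_days  # Apr-Oct: 214 days
#' @export
derive_growing_season <- function(climate, warm_threshold = 0,
                                  strict = FALSE) {
  stopifnot(inherits(climate, "monthly_climate"))
  temp <- climate$temp
  srad <- climate$srad
  warm <- if (strict) !is.na(temp) & temp > warm_threshold
          else !is.na(temp) & temp >= warm_threshold
  months_used <- which(warm)
  g_days <- sum(climate$month_days[months_used])
  if (length(months_used) == 0L) {
    g_temp <- NA_real_
    g_srad <- NA_real_
  } else {
    g_temp <- mean(temp[months_used])
    srad_in <- srad[months_used]
    g_srad <- if (all(is.na(srad_in))) NA_real_ else mean(srad_in, na.rm = TRUE)
  }
  complete <- !anyNA(temp) && !anyNA(srad)
  structure(list(g_days = as.integer(g_days), g_temp = g_temp,
                 g_srad = g_srad, months_used = months_used,
                 complete = complete),
            class = "growing_season")
}

#' @export
print.growing_season <- function(x, ...) {
  cat(sprintf(
    "Growing season: %d days over %d month(s); G_t = %s degC, G_srad = %s kJ/m^2/day%s\n",
    x$g_days, length(x$months_used),
    format(x$g_temp, digits = 4), format(x$g_srad, digits = 5),
    if (x$complete) "" else " [incomplete climate]"
  ))
  invisible(x)
}
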