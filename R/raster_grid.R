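#' Georeferenced single-band raster grid (ESRI ASCII format)
#'
#' A minimal in-memory raster: a numeric matrix of cell values on a regular
#' grid in geographic coordinates (longitude/latitude, WGS84), plus the
#' lower-left corner, the cell size and the NoData sentinel.  This is the
#' ESRI ASCII grid model; files are read and written with
#' [read_ascii_grid()] / [write_ascii_grid()], a plain-text format every
#' GIS stack (GDAL, terra, QGIS) understands.
#'
#' Row 1 of `values` is the northernmost row (as in the file format).
#'
#' @param values Numeric matrix, `nrows x ncols`, top row = north.
#'   `NA` entries are NoData.
#' @param xll,yll Longitude/latitude of the lower-left corner of the grid.
#' @param cellsize Cell edge length in decimal degrees.
#' @param nodata NoData sentinel written to file (default -9999).
#' @return An object of class `ascii_grid`.
#' @export
ascii_grid <- function(values, xll, yll, cellsize, nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cellsize <= 0) stop("ascii_grid: cellsize must be > 0")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata,
                 ncols = ncol(values), nrows = nrow(values)),
            class = "ascii_grid")
}

#' @rdname ascii_grid
#' @param path File path of an ESRI ASCII grid (`.asc`).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("read_ascii_grid: file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]])) stop("read_ascii_grid: header lacks ", key)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("read_ascii_grid: expected ", hdr$ncols * hdr$nrows,
         " cell values, found ", length(vals))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  ascii_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' @rdname ascii_grid
#' @param grid An `ascii_grid` object.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ascii_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$ncols),
    paste("nrows", grid$nrows),
    paste("xllcorner", format(grid$xll, digits = 15)),
    paste("yllcorner", format(grid$yll, digits = 15)),
    paste("cellsize", format(grid$cellsize, digits = 15)),
    paste("NODATA_value", grid$nodata)
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Longitude/latitude of every cell center; rows top-down as stored.
grid_cell_centers <- function(grid) {
  lon <- grid$xll + (seq_len(grid$ncols) - 0.5) * grid$cellsize
  lat <- grid$yll + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cellsize
  list(lon = lon, lat = lat)
}

# Value of the cell containing (lon, lat); NA if outside the extent
# (distinguished from an in-extent NoData cell by the "outside" attribute).
grid_value_at <- function(grid, lon, lat) {
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row <- grid$nrows - floor((lat - grid$yll) / grid$cellsize)
  if (col < 1 || col > grid$ncols || row < 1 || row > grid$nrows) {
    return(structure(NA_real_, outside = TRUE))
  }
  grid$values[row, col]
}

#' Great-circle distance in meters
#'
#' Haversine distance on a WGS84 mean sphere (radius 6371008.8 m).  Used to
#' decide which raster cells fall inside a metric buffer around a site; a
#' circle of great-circle radius r is exactly the circular buffer drawn in a
#' local azimuthal-equidistant projection centred on the site.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorised).
#' @return Distance(s) in meters.
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  R <- 6371008.8
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# Mean over valid cells whose centers lie within buffer_m of the site.
# Returns NA when no valid cell center falls inside the buffer.
grid_buffer_mean <- function(grid, lon, lat, buffer_m) {
  cc <- grid_cell_centers(grid)
  lonm <- matrix(cc$lon, grid$nrows, grid$ncols, byrow = TRUE)
  latm <- matrix(cc$lat, grid$nrows, grid$ncols)
  d <- haversine_m(lon, lat, lonm, latm)
  inside <- d <= buffer_m & !is.na(grid$values)
  if (!any(inside)) return(NA_real_)
  mean(grid$values[inside])
}

#' Extract monthly climate for sites from raster stacks
#'
#' Samples 12 temperature and 12 solar-radiation rasters (one file per
#' month, January first) at each site's coordinates.  Without a buffer the
#' value of the cell containing the point is used; with `buffer_m` the
#' unweighted mean of all valid (non-NoData) cells whose centers fall
#' within a circle of that great-circle radius is used.  NoData at a
#' site/month is recorded as a missing month.  Sites outside the raster
#' extent are flagged and carry an all-missing climate.
#'
#' Rasters must be ESRI ASCII grids in geographic coordinates sharing one
#' grid definition per variable.
#'
#' @param sites Data.frame with columns `site_id`, `lon`, `lat`
#'   (see [read_sites()]).
#' @param temp_rasters Character vector of 12 file paths, month order.
#' @param srad_rasters Character vector of 12 file paths, month order.
#' @param buffer_m Optional buffer radius in meters.
#' @return Named list mapping `site_id` to [monthly_climate()]; sites
#'   outside the extent are listed in the `outside_extent` attribute.
#' @export
extract_monthly <- function(sites, temp_rasters, srad_rasters,
                            buffer_m = NULL) {
  if (length(temp_rasters) != 12L || length(srad_rasters) != 12L) {
    stop("extract_monthly: exactly 12 rasters required per variable (got ",
         length(temp_rasters), " temp, ", length(srad_rasters), " srad)")
  }
  tg <- lapply(temp_rasters, read_ascii_grid)
  sg <- lapply(srad_rasters, read_ascii_grid)
  same_geom <- function(a, b) {
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize, a$ncols, a$nrows),
                     c(b$xll, b$yll, b$cellsize, b$ncols, b$nrows)))
  }
  for (g in c(tg[-1], sg)) {
    if (!same_geom(tg[[1]], g)) {
      stop("extract_monthly: rasters do not share one grid definition")
    }
  }
  sample_one <- function(grid, lon, lat) {
    if (is.null(buffer_m)) grid_value_at(grid, lon, lat)
    else grid_buffer_mean(grid, lon, lat, buffer_m)
  }
  out <- vector("list", nrow(sites))
  names(out) <- as.character(sites$site_id)
  outside <- character(0)
  for (i in seq_len(nrow(sites))) {
    lon <- sites$lon[i]; lat <- sites$lat[i]
    tv <- vapply(tg, sample_one, numeric(1), lon = lon, lat = lat)
    sv <- vapply(sg, sample_one, numeric(1), lon = lon, lat = lat)
    if (all(is.na(tv)) && all(is.na(sv))) {
      outside <- c(outside, as.character(sites$site_id[i]))
    }
    sv[!is.na(sv) & sv < 0] <- NA_real_  # radiation cannot be negative
    out[[i]] <- monthly_climate(tv, sv)
  }
  if (length(outside) > 0) {
    warning("extract_monthly: site(s) with no extractable climate ",
            "(outside extent or all NoData): ",
            paste(outside, collapse = ", "))
  }
  attr(out, "outside_extent") <- outside
  out
}
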