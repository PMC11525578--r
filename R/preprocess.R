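#' Temperature normalization specification
#'
#' Affine map taking the interval `[t_min, t_max]` in degrees Celsius to
#' `[0, 1]`. The defaults map -13 degC to 0 and 47 degC to 1. The map is not
#' a saturation: values outside the interval are transformed linearly to
#' values outside `[0, 1]` (warmer-world inputs may locally exceed `t_max`).
#'
#' @param t_min,t_max interval bounds in degrees Celsius; `t_max > t_min`.
#' @return an object of class `normalization_spec`.
#' @export
normalization_spec <- function(t_min = -13, t_max = 47) {
  if (!is.finite(t_min) || !is.finite(t_max) || t_max <= t_min) {
    stop("normalization requires finite t_max > t_min", call. = FALSE)
  }
  structure(list(t_min = t_min, t_max = t_max), class = "normalization_spec")
}

#' Monthly maximum of sub-monthly temperature fields
#'
#' Reduces a stack of sub-monthly (e.g. hourly or daily) fields to one field
#' per calendar month, each cell holding the maximum over that month's
#' timestamps. Months are calendar months in UTC. The reduction is idempotent:
#' applied to already-monthly data it returns the data unchanged.
#'
#' @param time POSIXct timestamps (any sub-monthly cadence), or a
#'   `temp_field_series` (already monthly; returned as-is).
#' @param values numeric array `[time x lat x lon]` aligned with `time`.
#' @param lat,lon grid axes in degrees.
#' @param scenario scenario label carried into the result.
#' @return a [temperature_field_series()] of monthly maxima.
#' @export
monthly_max <- function(time, values = NULL, lat = NULL, lon = NULL,
                        scenario = "reference") {
  if (inherits(time, "temp_field_series")) return(time)
  stopifnot(inherits(time, "POSIXct"), is.array(values))
  key <- format(time, "%Y-%m", tz = "UTC")
  ym <- unique(key)
  years <- as.integer(substr(ym, 1, 4))
  mons <- as.integer(substr(ym, 6, 7))
  ord <- order(month_index(years, mons))
  ym <- ym[ord]; years <- years[ord]; mons <- mons[ord]
  counts <- table(key)[ym]
  if (any(counts == 0L) || anyNA(counts)) {
    stop("month with zero timestamps in input span", call. = FALSE)
  }
  idx <- month_index(years, mons)
  if (any(diff(idx) != 1L)) {
    gap <- which(diff(idx) != 1L)[1]
    stop(sprintf("no timestamps for month(s) after %s", ym[gap]), call. = FALSE)
  }
  out <- array(NA_real_, dim = c(length(ym), length(lat), length(lon)))
  for (k in seq_along(ym)) {
    sel <- key == ym[k]
    out[k, , ] <- apply(values[sel, , , drop = FALSE], c(2L, 3L), max)
  }
  temperature_field_series(data.frame(year = years, month = mons),
                           lat, lon, out, scenario = scenario)
}

#' Subset a gridded series to a lon/lat box
#'
#' Keeps the grid cells whose centers lie inside the closed box. The default
#' box, 10W-40E x 30N-65N, selects 51 x 36 cells on a 1-degree grid.
#'
#' @param series a [temperature_field_series()].
#' @param lon_range,lat_range length-2 numeric bounds in degrees (closed).
#' @return the restricted `temp_field_series`.
#' @export
subset_domain <- function(series, lon_range = c(-10, 40), lat_range = c(30, 65)) {
  stopifnot(inherits(series, "temp_field_series"))
  ilon <- which(series$lon >= lon_range[1] & series$lon <= lon_range[2])
  ilat <- which(series$lat >= lat_range[1] & series$lat <= lat_range[2])
  if (length(ilon) == 0L || length(ilat) == 0L) {
    stop("requested box does not intersect the grid", call. = FALSE)
  }
  temperature_field_series(series$months, series$lat[ilat], series$lon[ilon],
                           series$values[, ilat, ilon, drop = FALSE],
                           scenario = series$scenario,
                           normalized = series$normalized)
}

#' Normalize temperatures to the unit interval
#'
#' Applies `v' = (v - t_min) / (t_max - t_min)` cell-wise. Values outside
#' `[t_min, t_max]` are mapped linearly outside `[0, 1]` -- they are *not*
#' clipped -- and a warning reports how many cells fall outside.
#'
#' @param series a [temperature_field_series()] in degrees Celsius.
#' @param spec a [normalization_spec()].
#' @return the normalized series (`normalized = TRUE`, dimensionless).
#' @seealso [denormalize_temperature()]
#' @export
normalize_temperature <- function(series, spec = normalization_spec()) {
  stopifnot(inherits(series, "temp_field_series"), inherits(spec, "normalization_spec"))
  if (series$normalized) stop("series is already normalized", call. = FALSE)
  v <- (series$values - spec$t_min) / (spec$t_max - spec$t_min)
  n_out <- sum(v < 0 | v > 1)
  if (n_out > 0L) {
    warning(sprintf(
      "%d cell value(s) outside [%g, %g] degC map outside [0,1] (not clipped)",
      n_out, spec$t_min, spec$t_max), call. = FALSE)
  }
  out <- series
  out$values <- v
  out$normalized <- TRUE
  out
}

#' Invert the temperature normalization
#'
#' @inheritParams normalize_temperature
#' @return the series back on the degrees-Celsius scale.
#' @export
denormalize_temperature <- function(series, spec = normalization_spec()) {
  stopifnot(inherits(series, "temp_field_series"), inherits(spec, "normalization_spec"))
  if (!series$normalized) stop("series is not normalized", call. = FALSE)
  out <- series
  out$values <- series$values * (spec$t_max - spec$t_min) + spec$t_min
  out$normalized <- FALSE
  out
}

#' Flatten monthly fields into network input vectors
#'
#' Each monthly 2D field becomes one column of a `K x T` matrix in a fixed,
#' documented cell order: latitude-major from north to south, and within each
#' latitude from west to east. The same order must be used for training and
#' for every prediction scenario; [unflatten_inputs()] inverts it.
#'
#' @param series a normalized [temperature_field_series()].
#' @return numeric matrix `K x T` with `K = n_lat * n_lon`; attributes `lat`,
#'   `lon` record the axes for order checks.
#' @export
flatten_inputs <- function(series) {
  stopifnot(inherits(series, "temp_field_series"))
  if (!series$normalized) {
    warning("flattening a non-normalized series; the network expects normalized inputs",
            call. = FALSE)
  }
  nlat <- length(series$lat); nlon <- length(series$lon)
  tdim <- nrow(series$months)
  # north-to-south = descending latitude
  lat_order <- order(series$lat, decreasing = TRUE)
  u <- matrix(NA_real_, nrow = nlat * nlon, ncol = tdim)
  for (t in seq_len(tdim)) {
    field <- matrix(series$values[t, , , drop = FALSE], nrow = nlat, ncol = nlon)
    u[, t] <- as.vector(t(field[lat_order, , drop = FALSE]))
  }
  dimnames(u) <- list(NULL, month_label(series$months$year, series$months$month))
  attr(u, "lat") <- series$lat
  attr(u, "lon") <- series$lon
  u
}

#' Invert [flatten_inputs()] for one month
#'
#' @param u numeric vector of length `n_lat * n_lon` in flattening order.
#' @param lat,lon the grid axes the vector was flattened from.
#' @return numeric matrix `[lat x lon]` with latitude ascending.
#' @export
unflatten_inputs <- function(u, lat, lon) {
  nlat <- length(lat); nlon <- length(lon)
  stopifnot(length(u) == nlat * nlon)
  m <- matrix(u, nrow = nlat, ncol = nlon, byrow = TRUE)
  m[rev(seq_len(nlat)), , drop = FALSE]  # back to ascending latitude
}

#' Check two series share grid and flattening order
#' @keywords internal
assert_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$lat, b$lat)) || !isTRUE(all.equal(a$lon, b$lon))) {
    stop("grid mismatch between scenarios: lat/lon axes differ", call. = FALSE)
  }
  invisible(TRUE)
}
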