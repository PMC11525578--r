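#' Monthly gridded temperature series
#'
#' Container for a time-ordered stack of 2D temperature fields on a regular
#' lon/lat grid: one field per calendar month, e.g. the monthly maximum of
#' hourly 2m temperature. This is the object every preprocessing step and the
#' network consume.
#'
#' @param months data.frame with integer columns `year`, `month`; must be
#'   consecutive calendar months.
#' @param lat,lon numeric vectors of cell-center coordinates in degrees,
#'   strictly increasing and regularly spaced.
#' @param values numeric array of dimension `c(nrow(months), length(lat),
#'   length(lon))`; degrees Celsius unless `normalized = TRUE`.
#' @param scenario scenario label, e.g. `"reference"`, `"plus2K"`, `"plus4K"`.
#' @param normalized logical; `TRUE` once [normalize_temperature()] has been
#'   applied (values then dimensionless).
#' @return an object of class `temp_field_series`.
#' @seealso [monthly_max()], [subset_domain()], [normalize_temperature()],
#'   [flatten_inputs()], [generate_temperature_series()]
#' @export
temperature_field_series <- function(months, lat, lon, values,
                                     scenario = "reference",
                                     normalized = FALSE) {
  months <- as.data.frame(months)
  stopifnot(all(c("year", "month") %in% names(months)))
  assert_consecutive_months(months)
  check_regular_axis(lat, "lat")
  check_regular_axis(lon, "lon")
  values <- as.array(values)
  if (length(dim(values)) != 3L ||
      !all(dim(values) == c(nrow(months), length(lat), length(lon)))) {
    stop(sprintf(
      "values must be a [time x lat x lon] array of dimension %d x %d x %d",
      nrow(months), length(lat), length(lon)), call. = FALSE)
  }
  if (!all(is.finite(values))) stop("values contain non-finite entries", call. = FALSE)
  structure(
    list(months = months, lat = as.numeric(lat), lon = as.numeric(lon),
         values = values, scenario = as.character(scenario),
         normalized = isTRUE(normalized)),
    class = "temp_field_series")
}

check_regular_axis <- function(x, name) {
  if (length(x) < 1L) stop(sprintf("%s axis is empty", name), call. = FALSE)
  if (length(x) > 1L) {
    d <- diff(x)
    if (any(d <= 0)) stop(sprintf("%s axis must be strictly increasing", name), call. = FALSE)
    if (max(d) - min(d) > 1e-8) {
      stop(sprintf("%s axis is not regularly spaced", name), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.temp_field_series <- function(x, ...) {
  m <- x$months
  cat(sprintf("<temp_field_series> %s, %d months (%s to %s), grid %d lat x %d lon%s\n",
              x$scenario, nrow(m),
              month_label(m$year[1], m$month[1]),
              month_label(m$year[nrow(m)], m$month[nrow(m)]),
              length(x$lat), length(x$lon),
              if (x$normalized) ", normalized" else " [degC]"))
  invisible(x)
}

#' @export
dim.temp_field_series <- function(x) dim(x$values)

#' Domain mean of each monthly field
#'
#' Average of the field over a lon/lat box (closed bounds on cell centers),
#' one value per month. Used both by the synthetic mortality response and for
#' diagnostics.
#'
#' @param series a [temperature_field_series()].
#' @param lon_range,lat_range length-2 numeric bounds in degrees; defaults
#'   cover the whole grid.
#' @return numeric vector, one value per month.
#' @export
domain_mean <- function(series, lon_range = range(series$lon),
                        lat_range = range(series$lat)) {
  stopifnot(inherits(series, "temp_field_series"))
  ilat <- which(series$lat >= lat_range[1] & series$lat <= lat_range[2])
  ilon <- which(series$lon >= lon_range[1] & series$lon <= lon_range[2])
  if (length(ilat) == 0L || length(ilon) == 0L) {
    stop("requested box does not intersect the grid", call. = FALSE)
  }
  apply(series$values[, ilat, ilon, drop = FALSE], 1L, mean)
}
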