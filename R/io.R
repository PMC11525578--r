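#' Write a temperature series to netCDF
#'
#' Writes a `(time, lat, lon)` stack with CF-style coordinate variables.
#' Time is encoded as "months since Jan of the first year" plus explicit
#' integer `year` and `month` variables, so the round trip is exact.
#'
#' @param series a [temperature_field_series()].
#' @param path output file path (".nc").
#' @param varname netCDF variable name; default `t2m_monthlymax`.
#' @return `path`, invisibly.
#' @export
write_temperature_nc <- function(series, path, varname = "t2m_monthlymax") {
  stopifnot(inherits(series, "temp_field_series"))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", series$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", series$lat)
  t0 <- series$months$year[1]
  tvals <- month_index(series$months$year, series$months$month) -
    month_index(t0, 1L)
  dim_time <- ncdf4::ncdim_def("time", sprintf("months since %d-01", t0),
                               tvals, unlim = TRUE)
  units <- if (series$normalized) "1" else "degC"
  var_t <- ncdf4::ncvar_def(varname, units, list(dim_lon, dim_lat, dim_time),
                            missval = NA_real_, prec = "double")
  var_y <- ncdf4::ncvar_def("year", "year", list(dim_time), prec = "integer")
  var_m <- ncdf4::ncvar_def("month", "month of year", list(dim_time),
                            prec = "integer")
  nc <- ncdf4::nc_create(path, list(var_t, var_y, var_m))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  # series$values is [time, lat, lon]; netCDF wants [lon, lat, time]
  ncdf4::ncvar_put(nc, var_t, aperm(series$values, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, var_y, series$months$year)
  ncdf4::ncvar_put(nc, var_m, series$months$month)
  ncdf4::ncatt_put(nc, 0, "scenario", series$scenario)
  ncdf4::ncatt_put(nc, 0, "normalized", as.integer(series$normalized))
  invisible(path)
}

#' Read a temperature series from netCDF
#'
#' Expects the layout written by [write_temperature_nc()]: a `(lon, lat,
#' time)` variable plus `year`/`month` time coordinates (falling back to a
#' "months since YYYY-01" time axis).
#'
#' @param path netCDF file path.
#' @param varname variable name; default `t2m_monthlymax`.
#' @return a [temperature_field_series()].
#' @export
read_temperature_nc <- function(path, varname = "t2m_monthlymax") {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  lon <- as.vector(nc$dim$lon$vals)
  lat <- as.vector(nc$dim$lat$vals)
  vals <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  if ("year" %in% names(nc$var)) {
    months <- data.frame(year = as.integer(ncdf4::ncvar_get(nc, "year")),
                         month = as.integer(ncdf4::ncvar_get(nc, "month")))
  } else {
    tu <- nc$dim$time$units
    y0 <- as.integer(sub("months since (\\d{4}).*", "\\1", tu))
    idx <- month_index(y0, 1L) + as.integer(nc$dim$time$vals)
    months <- data.frame(year = idx %/% 12L, month = idx %% 12L + 1L)
  }
  scen <- ncdf4::ncatt_get(nc, 0, "scenario")
  norm <- ncdf4::ncatt_get(nc, 0, "normalized")
  temperature_field_series(
    months, lat, lon, aperm(vals, c(3, 2, 1)),
    scenario = if (scen$hasatt) scen$value else "reference",
    normalized = norm$hasatt && norm$value == 1L)
}

#' Write / read a mortality series as CSV
#'
#' Columns: `year, month, deaths, population, rate_per_100k`. This mirrors
#' what national deaths (monthly, all-cause) and population (annual,
#' interpolated) tables reduce to after preprocessing.
#'
#' @param x a [mortality_series()].
#' @param path CSV path.
#' @return `path` invisibly; the reader returns a [mortality_series()].
#' @export
write_mortality_csv <- function(x, path) {
  stopifnot(inherits(x, "mortality_series"))
  df <- data.frame(year = x$year, month = x$month, deaths = x$deaths,
                   population = x$population, rate_per_100k = x$rate)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mortality_csv
#' @export
read_mortality_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "month", "deaths", "population")
  if (!all(need %in% names(df))) {
    stop(sprintf("mortality CSV must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  rate <- if ("rate_per_100k" %in% names(df)) df$rate_per_100k else NULL
  mortality_series(df[, c("year", "month")], df$deaths, df$population, rate)
}

#' Read deaths and population tables and assemble a mortality series
#'
#' Mirrors the national statistics exports this pipeline targets: a monthly
#' all-cause deaths table (as in regionalstatistik code 12613-03-01-4-B) and
#' an annual population table (code 12411-05-01-4-B). Per-region columns, if
#' present, are summed to a national total before the rate is formed (deaths
#' summed over regions divided by summed population).
#'
#' @param deaths_csv CSV with columns `year`, `month`, and either `deaths`
#'   or one column per region.
#' @param population_csv CSV with columns `year`, and either `population` or
#'   one column per region (annual values).
#' @return a [mortality_series()] with population interpolated to months.
#' @export
read_mortality_tables <- function(deaths_csv, population_csv) {
  d <- utils::read.csv(deaths_csv)
  p <- utils::read.csv(population_csv)
  if (!all(c("year", "month") %in% names(d))) {
    stop("deaths CSV must have year and month columns", call. = FALSE)
  }
  if (!"year" %in% names(p)) stop("population CSV must have a year column", call. = FALSE)
  dcols <- setdiff(names(d), c("year", "month"))
  pcols <- setdiff(names(p), "year")
  deaths <- if (length(dcols) == 1L) d[[dcols]] else rowSums(d[, dcols, drop = FALSE])
  pop_annual <- if (length(pcols) == 1L) p[[pcols]] else rowSums(p[, pcols, drop = FALSE])
  ord <- order(month_index(d$year, d$month))
  months <- data.frame(year = d$year[ord], month = d$month[ord])
  pop_m <- interpolate_population(
    data.frame(year = p$year, population = pop_annual), months)
  mortality_series(months, deaths[ord], pop_m)
}

#' Write a tidy month/rate/scenario CSV
#'
#' One row per month and scenario with the ensemble mean, SD, reference rate
#' and difference -- the results-bundle format of the scenario analysis.
#'
#' @param comparisons named list of `scenario_comparison` objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparisons, path) {
  rows <- lapply(names(comparisons), function(s) {
    cbind(scenario = s, comparisons[[s]]$monthly)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
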