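#' Synthetic storyline climate specification
#'
#' Parameters of the seeded generator that emulates monthly-maximum 2m
#' temperature fields of a storyline simulation: a Northern-Hemisphere
#' seasonal cycle with a meridional gradient, spatially correlated weather
#' noise, occasional summer heat waves, and a scenario warming offset whose
#' local extremes can be amplified beyond the mean offset.
#'
#' The generator consumes its random-number stream in an order that does not
#' depend on `warming_offset` or `extreme_amplification`, so two specs
#' differing only in those fields produce fields that differ by a
#' deterministic amount (exactly `warming_offset` everywhere when
#' `extreme_amplification = 1`).
#'
#' @param lon_range,lat_range grid extents in degrees (closed, cell centers);
#'   defaults 10W-40E and 30N-65N.
#' @param resolution grid spacing in degrees.
#' @param months data.frame of consecutive `year`, `month` rows; default
#'   Jan 2015 - Dec 2019.
#' @param mean_level climatological monthly-max temperature (degC) at the
#'   reference latitude (the mid-latitude of `lat_range`).
#' @param lat_gradient cooling per degree latitude northward (K/degree).
#' @param seasonal_amplitude half peak-to-trough seasonal swing (K), peaking
#'   in July.
#' @param spatial_corr_length Gaussian correlation length of the weather
#'   noise (degrees); 0 disables smoothing.
#' @param heatwave_rate expected heat-wave events per summer (Jun-Aug).
#' @param heatwave_magnitude typical peak amplitude of a heat-wave bump (K).
#' @param heatwave_extent Gaussian footprint scale of a heat wave (degrees).
#' @param warming_offset scenario mean warming in K; 0, 2 or 4 for the
#'   reference, +2K and +4K storylines.
#' @param extreme_amplification >= 1; heat-wave magnitudes are scaled by
#'   `1 + (extreme_amplification - 1) * warming_offset / 4`, so warmer
#'   scenarios show local exceedances above the mean offset while the
#'   reference fields are unchanged.
#' @param noise_sd standard deviation of the correlated weather noise (K).
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   output.
#' @return an object of class `synthetic_climate_spec`.
#' @export
synthetic_climate_spec <- function(lon_range = c(-10, 40), lat_range = c(30, 65),
                                   resolution = 1,
                                   months = month_seq(c(2015, 1), c(2019, 12)),
                                   mean_level = 17, lat_gradient = 0.4,
                                   seasonal_amplitude = 12,
                                   spatial_corr_length = 3,
                                   heatwave_rate = 2, heatwave_magnitude = 5,
                                   heatwave_extent = 4,
                                   warming_offset = 0,
                                   extreme_amplification = 1.5,
                                   noise_sd = 1.5, seed = 1L) {
  if (!is.numeric(resolution) || resolution <= 0) {
    stop("resolution must be positive", call. = FALSE)
  }
  months <- as.data.frame(months)
  if (nrow(months) == 0L) stop("month list must be non-empty", call. = FALSE)
  assert_consecutive_months(months)
  if (!warming_offset %in% c(0, 2, 4)) {
    warning("warming_offset outside the study's {0, 2, 4} K scenarios", call. = FALSE)
  }
  if (extreme_amplification < 1) {
    stop("extreme_amplification must be >= 1", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, heatwave_rate >= 0, seasonal_amplitude >= 0)
  structure(list(
    lon_range = lon_range, lat_range = lat_range, resolution = resolution,
    months = months, mean_level = mean_level, lat_gradient = lat_gradient,
    seasonal_amplitude = seasonal_amplitude,
    spatial_corr_length = spatial_corr_length,
    heatwave_rate = heatwave_rate, heatwave_magnitude = heatwave_magnitude,
    heatwave_extent = heatwave_extent, warming_offset = warming_offset,
    extreme_amplification = extreme_amplification,
    noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_climate_spec")
}

#' Synthetic temperature-to-mortality response specification
#'
#' Ground-truth monthly mortality response used to manufacture target data
#' with recoverable structure: a baseline rate, a seasonal cycle peaking in
#' winter, a heat-excess hinge term driven by the domain-mean monthly maximum
#' over a Germany-covering box, a cold/respiratory hinge term, and Gaussian
#' observation noise. Rates are deaths per 100,000 inhabitants per month.
#'
#' @param baseline_rate mean rate (per 100,000/month).
#' @param seasonal_rate_amplitude amplitude of the seasonal cosine, peaking
#'   in January (rate units).
#' @param heat_coefficient rate increase per K of domain-mean monthly maximum
#'   above `heat_threshold`.
#' @param heat_threshold degC.
#' @param winter_coefficient rate increase per K of domain-mean monthly
#'   maximum below `cold_threshold`.
#' @param cold_threshold degC.
#' @param noise_sd observation noise SD (rate units); >= 0.
#' @param population annual inhabitants: a scalar, a named vector
#'   (names = years), or a data.frame `year`/`population`.
#' @param box_lon,box_lat the sub-box whose domain mean drives the response;
#'   defaults roughly cover Germany.
#' @param seed integer seed for the observation noise.
#' @return an object of class `synthetic_response_spec`.
#' @export
synthetic_response_spec <- function(baseline_rate = 90,
                                    seasonal_rate_amplitude = 8,
                                    heat_coefficient = 2.5, heat_threshold = 27,
                                    winter_coefficient = 1.2, cold_threshold = 8,
                                    noise_sd = 1, population = 83e6,
                                    box_lon = c(5, 15), box_lat = c(47, 55),
                                    seed = 1L) {
  coefs <- c(baseline_rate, seasonal_rate_amplitude, heat_coefficient,
             heat_threshold, winter_coefficient, cold_threshold)
  if (any(!is.finite(coefs))) stop("response coefficients must be finite", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  pop <- if (is.data.frame(population)) population$population else as.numeric(population)
  if (any(!is.finite(pop)) || any(pop <= 0)) {
    stop("population must be positive", call. = FALSE)
  }
  structure(list(
    baseline_rate = baseline_rate,
    seasonal_rate_amplitude = seasonal_rate_amplitude,
    heat_coefficient = heat_coefficient, heat_threshold = heat_threshold,
    winter_coefficient = winter_coefficient, cold_threshold = cold_threshold,
    noise_sd = noise_sd, population = population,
    box_lon = box_lon, box_lat = box_lat, seed = as.integer(seed)),
    class = "synthetic_response_spec")
}

#' Generate a synthetic monthly-maximum temperature series
#'
#' Builds one 2D field per month as climatology + correlated weather noise +
#' summer heat-wave bumps + the scenario warming offset. Spatial correlation
#' comes from Gaussian-kernel smoothing of white noise at the stated
#' correlation length; heat waves are additive Gaussian bumps with random
#' centers, summer-only (Jun-Aug), with Poisson-distributed event counts.
#'
#' @param spec a [synthetic_climate_spec()].
#' @return a [temperature_field_series()] labelled by the warming offset
#'   (`reference`, `plus2K`, `plus4K`, or `plus<w>K`).
#' @export
generate_temperature_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_climate_spec"))
  lon <- seq(spec$lon_range[1], spec$lon_range[2], by = spec$resolution)
  lat <- seq(spec$lat_range[1], spec$lat_range[2], by = spec$resolution)
  nlat <- length(lat); nlon <- length(lon)
  months <- spec$months
  tdim <- nrow(months)
  lat_ref <- mean(spec$lat_range)

  amp_factor <- 1 + (spec$extreme_amplification - 1) * spec$warming_offset / 4

  values <- array(0, dim = c(tdim, nlat, nlon))
  old_seed <- local_rng(spec$seed)
  on.exit(restore_rng(old_seed), add = TRUE)

  clim_lat <- spec$mean_level - spec$lat_gradient * (lat - lat_ref)
  for (t in seq_len(tdim)) {
    mo <- months$month[t]
    seasonal <- spec$seasonal_amplitude * cos(2 * pi * (mo - 7) / 12)
    field <- matrix(rep(clim_lat + seasonal, nlon), nrow = nlat)
    if (spec$noise_sd > 0) {
      field <- field + correlated_noise(nlat, nlon, spec$spatial_corr_length /
                                          spec$resolution, spec$noise_sd)
    } else {
      # keep the RNG stream aligned across noise settings is NOT required;
      # only offset/amplification must leave the stream untouched
    }
    if (mo %in% 6:8 && spec$heatwave_rate > 0) {
      n_ev <- stats::rpois(1L, spec$heatwave_rate / 3)
      for (e in seq_len(n_ev)) {
        c_lat <- stats::runif(1, min(lat), max(lat))
        c_lon <- stats::runif(1, min(lon), max(lon))
        mag <- spec$heatwave_magnitude * stats::runif(1, 0.5, 1.5) * amp_factor
        d2 <- outer((lat - c_lat)^2, (lon - c_lon)^2, "+")
        field <- field + mag * exp(-d2 / (2 * spec$heatwave_extent^2))
      }
    }
    values[t, , ] <- field + spec$warming_offset
  }
  scen <- if (spec$warming_offset == 0) "reference"
          else sprintf("plus%gK", spec$warming_offset)
  temperature_field_series(months, lat, lon, values, scenario = scen)
}

#' Generate a synthetic mortality series from temperature fields
#'
#' Evaluates the ground-truth response on the domain-mean monthly maximum of
#' the response box: `rate = baseline + seasonal + heat_coefficient *
#' max(0, dm - heat_threshold) + winter_coefficient * max(0, cold_threshold -
#' dm) + noise`. Deaths are expected counts, `rate * population / 1e5`
#' (non-integer by design, so rate and deaths stay exactly consistent).
#'
#' @param temps a [temperature_field_series()] in degrees Celsius covering at
#'   least 24 months.
#' @param resp a [synthetic_response_spec()].
#' @return a [mortality_series()].
#' @export
generate_mortality_series <- function(temps, resp) {
  stopifnot(inherits(temps, "temp_field_series"),
            inherits(resp, "synthetic_response_spec"))
  if (temps$normalized) {
    stop("mortality response is defined on degrees Celsius, not normalized values",
         call. = FALSE)
  }
  if (nrow(temps$months) < 24L) {
    stop("need at least 24 months of temperature data", call. = FALSE)
  }
  dm <- domain_mean(temps, resp$box_lon, resp$box_lat)
  rate <- synthetic_rate_closed_form(temps$months$month, dm, resp)
  if (resp$noise_sd > 0) {
    old_seed <- local_rng(resp$seed)
    on.exit(restore_rng(old_seed), add = TRUE)
    rate <- rate + stats::rnorm(length(rate), sd = resp$noise_sd)
  }
  if (is.numeric(resp$population) && length(resp$population) == 1L &&
      is.null(names(resp$population))) {
    pop_m <- rep(resp$population, length(rate))
  } else {
    pop_m <- interpolate_population(resp$population, temps$months)
  }
  deaths <- rate * pop_m / 1e5
  mortality_series(temps$months, deaths, pop_m, rate)
}

#' Noise-free closed-form synthetic mortality rate
#'
#' The deterministic part of the synthetic response, exposed so tests and
#' diagnostics can evaluate the ground truth directly from a domain-mean
#' temperature series.
#'
#' @param month integer months (1-12).
#' @param dm domain-mean monthly-maximum temperature (degC), same length.
#' @param resp a [synthetic_response_spec()].
#' @return numeric rate vector (per 100,000/month), without noise.
#' @export
synthetic_rate_closed_form <- function(month, dm, resp) {
  resp$baseline_rate +
    resp$seasonal_rate_amplitude * cos(2 * pi * (month - 1) / 12) +
    resp$heat_coefficient * pmax(0, dm - resp$heat_threshold) +
    resp$winter_coefficient * pmax(0, resp$cold_threshold - dm)
}

# Gaussian-smoothed white noise with interior SD `sd`; sigma in grid cells.
correlated_noise <- function(nlat, nlon, sigma, sd) {
  w <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
  if (sigma <= 0) return(w * sd)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k <- k / sum(k)
  sm <- smooth_separable(w, k)
  # variance of kernel-smoothed unit white noise in the grid interior
  sm * sd / sqrt(sum(k^2)^2)
}

# separable 1D convolution along both axes, edge-renormalized
smooth_separable <- function(m, k) {
  conv1 <- function(v) {
    n <- length(v)
    out <- stats::filter(c(rep(0, length(k) %/% 2), v, rep(0, length(k) %/% 2)),
                         k, sides = 2)
    wts <- stats::filter(c(rep(0, length(k) %/% 2), rep(1, n),
                           rep(0, length(k) %/% 2)), k, sides = 2)
    pad <- length(k) %/% 2
    (out / wts)[pad + seq_len(n)]
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(m2, 1L, conv1))
}

# Seed the session RNG locally; returns the previous state for restore_rng().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
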