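#' Monthly mortality series
#'
#' Monthly all-cause deaths together with the (interpolated) population and
#' the derived mortality rate per 100,000 inhabitants. Deaths may be
#' non-integer when they are expected counts from the synthetic generator.
#'
#' @param months data.frame with columns `year`, `month` (consecutive).
#' @param deaths numeric vector of monthly death counts.
#' @param population numeric vector of monthly inhabitants (interpolated from
#'   annual figures, see [interpolate_population()]); must be positive.
#' @param rate optional; computed as `deaths / population * 1e5` when omitted.
#' @return a data.frame of class `mortality_series` with columns `year`,
#'   `month`, `deaths`, `population`, `rate`.
#' @export
mortality_series <- function(months, deaths, population, rate = NULL) {
  months <- as.data.frame(months)
  assert_consecutive_months(months)
  n <- nrow(months)
  stopifnot(length(deaths) == n, length(population) %in% c(1L, n))
  population <- rep_len(population, n)
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("population must be positive and finite", call. = FALSE)
  }
  if (is.null(rate)) rate <- compute_rate(deaths, population)
  stopifnot(length(rate) == n)
  structure(
    data.frame(year = months$year, month = months$month,
               deaths = deaths, population = population, rate = rate),
    class = c("mortality_series", "data.frame"))
}

#' @export
print.mortality_series <- function(x, ...) {
  cat(sprintf("<mortality_series> %d months (%s to %s), mean rate %.1f per 100,000\n",
              nrow(x), month_label(x$year[1], x$month[1]),
              month_label(x$year[nrow(x)], x$month[nrow(x)]),
              mean(x$rate)))
  NextMethod()
}

#' Mortality rate per 100,000 inhabitants
#'
#' @param deaths numeric death counts.
#' @param population numeric inhabitants; must be positive.
#' @return `deaths / population * 1e5`.
#' @examples
#' compute_rate(800, 80e6)    # 1
#' compute_rate(72000, 80e6)  # 90
#' @export
compute_rate <- function(deaths, population) {
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("population must be positive", call. = FALSE)
  }
  deaths / population * 1e5
}

#' Restrict a mortality series to a month span
#'
#' @param x a [mortality_series()].
#' @param from,to `c(year, month)` inclusive bounds.
#' @return the restricted `mortality_series`.
#' @export
window_mortality <- function(x, from, to) {
  stopifnot(inherits(x, "mortality_series"))
  idx <- month_index(x$year, x$month)
  keep <- idx >= month_index(from[1], from[2]) & idx <= month_index(to[1], to[2])
  if (!any(keep)) stop("requested span not covered by the series", call. = FALSE)
  mortality_series(x[keep, c("year", "month")], x$deaths[keep],
                   x$population[keep], x$rate[keep])
}

#' Interpolate annual population to monthly values
#'
#' Annual population figures are anchored to July of their year (the middle
#' of the year on a month-index axis) and linearly interpolated between
#' anchors; before the first and after the last anchor the series is held
#' constant rather than extrapolated.
#'
#' @param annual named numeric vector (names = years) or a data.frame with
#'   columns `year` and `population`.
#' @param months target months, a data.frame with `year` and `month` columns.
#' @return numeric vector of monthly inhabitants, one per target month.
#' @examples
#' ann <- data.frame(year = c(2018, 2019), population = c(80e6, 82e6))
#' mon <- month_seq(c(2019, 1), c(2019, 1))
#' interpolate_population(ann, mon)  # 81e6: midpoint of the two July anchors
#' @export
interpolate_population <- function(annual, months) {
  if (is.data.frame(annual)) {
    years <- annual$year; pop <- annual$population
  } else {
    years <- as.integer(names(annual)); pop <- as.numeric(annual)
  }
  if (length(pop) < 1L) stop("need at least one annual population value", call. = FALSE)
  if (any(!is.finite(pop)) || any(pop <= 0)) {
    stop("population must be positive", call. = FALSE)
  }
  o <- order(years)
  anchors <- month_index(years[o], rep(7L, length(years)))
  target <- month_index(months$year, months$month)
  if (length(pop) == 1L) return(rep(pop, length(target)))
  stats::approx(anchors, pop[o], xout = target, rule = 2)$y
}
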