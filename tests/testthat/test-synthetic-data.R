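test_that("temperature generation is deterministic given the seed", {
  s <- tiny_climate_spec(seed = 7L)
  a <- generate_temperature_series(s)
  b <- generate_temperature_series(s)
  expect_identical(a$values, b$values)
  expect_identical(a$months, b$months)
})

test_that("warming offset shifts fields by exactly the offset", {
  base <- tiny_climate_spec(noise_sd = 0, heatwave_rate = 0, seed = 3L)
  plus4 <- tiny_climate_spec(noise_sd = 0, heatwave_rate = 0, seed = 3L,
                             warming_offset = 4)
  a <- generate_temperature_series(base)
  b <- generate_temperature_series(plus4)
  expect_equal(b$values - a$values, array(4, dim = dim(a$values)))
})

test_that("offset linearity holds with shared seed and amplification 1", {
  # full stochastic generator: noise + heat waves, amplification neutral
  base <- tiny_climate_spec(seed = 11L, extreme_amplification = 1)
  plus2 <- tiny_climate_spec(seed = 11L, extreme_amplification = 1,
                             warming_offset = 2)
  a <- generate_temperature_series(base)
  b <- generate_temperature_series(plus2)
  expect_equal(b$values, a$values + 2, tolerance = 1e-12)
})

test_that("amplification raises warm-scenario extremes above the mean offset", {
  base <- tiny_climate_spec(seed = 5L, extreme_amplification = 2)
  plus4 <- tiny_climate_spec(seed = 5L, extreme_amplification = 2,
                             warming_offset = 4)
  a <- generate_temperature_series(base)
  b <- generate_temperature_series(plus4)
  d <- b$values - a$values
  expect_true(all(d >= 4 - 1e-9))
  expect_gt(max(d), 4 + 0.5)  # some local exceedance well above the offset
})

test_that("seasonal cycle peaks in summer", {
  s <- generate_temperature_series(tiny_climate_spec(seed = 2L))
  dm <- domain_mean(s)
  expect_gt(mean(dm[s$months$month == 7]), mean(dm[s$months$month == 1]))
})

test_that("climate spec validates its inputs", {
  expect_error(synthetic_climate_spec(resolution = 0), "resolution")
  expect_error(synthetic_climate_spec(months = data.frame(year = integer(),
                                                          month = integer())),
               "non-empty")
  expect_error(synthetic_climate_spec(extreme_amplification = 0.5),
               "amplification")
  expect_warning(synthetic_climate_spec(warming_offset = 3), "scenario")
})

test_that("mortality with all modulation off is the constant baseline", {
  temps <- generate_temperature_series(tiny_climate_spec(seed = 1L))
  resp <- synthetic_response_spec(noise_sd = 0, heat_coefficient = 0,
                                  winter_coefficient = 0,
                                  seasonal_rate_amplitude = 0)
  m <- generate_mortality_series(temps, resp)
  expect_equal(m$rate, rep(resp$baseline_rate, nrow(m)))
  expect_equal(m$deaths, m$rate * m$population / 1e5)
})

test_that("noise-free mortality matches an independent formula evaluation", {
  temps <- generate_temperature_series(tiny_climate_spec(seed = 4L))
  resp <- synthetic_response_spec(noise_sd = 0)
  m <- generate_mortality_series(temps, resp)

  # spreadsheet-style recomputation: per-cell loop mean over the box, then
  # the closed-form response, all outside the generator's code path
  ilat <- which(temps$lat >= resp$box_lat[1] & temps$lat <= resp$box_lat[2])
  ilon <- which(temps$lon >= resp$box_lon[1] & temps$lon <= resp$box_lon[2])
  for (t in c(1, 7, 19, 30, 60)) {
    acc <- 0; n <- 0
    for (i in ilat) for (j in ilon) {
      acc <- acc + temps$values[t, i, j]; n <- n + 1
    }
    dm <- acc / n
    mo <- temps$months$month[t]
    expected <- resp$baseline_rate +
      resp$seasonal_rate_amplitude * cos(2 * pi * (mo - 1) / 12) +
      resp$heat_coefficient * max(0, dm - resp$heat_threshold) +
      resp$winter_coefficient * max(0, resp$cold_threshold - dm)
    expect_equal(m$rate[t], expected, tolerance = 1e-12)
  }
})

test_that("warmer summers raise mortality wherever the heat threshold is exceeded", {
  base <- tiny_climate_spec(seed = 9L, extreme_amplification = 1)
  plus4 <- tiny_climate_spec(seed = 9L, extreme_amplification = 1,
                             warming_offset = 4)
  ta <- generate_temperature_series(base)
  tb <- generate_temperature_series(plus4)
  resp <- synthetic_response_spec(noise_sd = 0)
  ma <- generate_mortality_series(ta, resp)
  mb <- generate_mortality_series(tb, resp)
  dm <- domain_mean(ta, resp$box_lon, resp$box_lat)
  summer_exceed <- ta$months$month %in% 6:8 & dm > resp$heat_threshold
  expect_true(any(summer_exceed))
  expect_true(all(mb$rate[summer_exceed] > ma$rate[summer_exceed]))
})

test_that("noise-free OLS on the hinge covariates recovers the response", {
  temps <- generate_temperature_series(tiny_climate_spec(seed = 12L))
  dm <- domain_mean(temps, c(5, 15), c(47, 55))

  # two-covariate form: seasonal term off
  resp <- synthetic_response_spec(noise_sd = 0, seasonal_rate_amplitude = 0,
                                  heat_coefficient = 3.1,
                                  winter_coefficient = 0.9)
  m <- generate_mortality_series(temps, resp)
  h_heat <- pmax(0, dm - resp$heat_threshold)
  h_cold <- pmax(0, resp$cold_threshold - dm)
  fit <- lm(m$rate ~ h_heat + h_cold)
  expect_equal(unname(coef(fit)[["h_heat"]]), resp$heat_coefficient,
               tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["h_cold"]]), resp$winter_coefficient,
               tolerance = 1e-6)

  # full design with the default seasonal amplitude
  resp2 <- synthetic_response_spec(noise_sd = 0)
  m2 <- generate_mortality_series(temps, resp2)
  seas <- cos(2 * pi * (temps$months$month - 1) / 12)
  fit2 <- lm(m2$rate ~ seas + h_heat + h_cold)
  expect_equal(unname(coef(fit2)[["h_heat"]]), resp2$heat_coefficient,
               tolerance = 1e-6)
  expect_equal(unname(coef(fit2)[["h_cold"]]), resp2$winter_coefficient,
               tolerance = 1e-6)
  expect_equal(unname(coef(fit2)[["seas"]]), resp2$seasonal_rate_amplitude,
               tolerance = 1e-6)
})

test_that("mortality generation rejects short or normalized inputs", {
  short <- generate_temperature_series(
    tiny_climate_spec(months = month_seq(c(2019, 1), c(2019, 12))))
  expect_error(generate_mortality_series(short, synthetic_response_spec()),
               "24 months")
  temps <- generate_temperature_series(tiny_climate_spec())
  normed <- suppressWarnings(normalize_temperature(temps))
  expect_error(generate_mortality_series(normed, synthetic_response_spec()),
               "normalized")
})
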