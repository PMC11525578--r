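# Small, fast fixture builders shared across the suite.

# 20 x 15 cell grid around Germany; 5 years monthly.
tiny_climate_spec <- function(...) {
  synthetic_climate_spec(lon_range = c(-2, 17), lat_range = c(44, 58),
                         spatial_corr_length = 2, ...)
}

# A minimal hand-built network with fully controlled weights (bypasses
# init_esn so update rules can be checked against scalar arithmetic).
toy_esn <- function(w_in, w, alpha = 1, lambda = 1e-8, washout = 0L) {
  n <- nrow(w)
  cfg <- esn_config(reservoir_size = n, alpha = alpha, ridge_lambda = lambda,
                    washout = washout, seed = 1L)
  structure(list(config = cfg, input_dim = ncol(w_in) - 1L,
                 W_in = w_in, W = w, W_out = NULL),
            class = "esn")
}

# Scalar-loop evaluation of the leaky-integrator update: the independent
# oracle for the state recursion.
oracle_update <- function(w_in, w, x_prev, u, alpha) {
  n <- nrow(w)
  drive <- numeric(n)
  for (i in seq_len(n)) {
    acc <- w_in[i, 1] * 1
    for (j in seq_along(u)) acc <- acc + w_in[i, j + 1] * u[j]
    for (j in seq_len(n)) acc <- acc + w[i, j] * x_prev[j]
    drive[i] <- acc
  }
  (1 - alpha) * x_prev + alpha * tanh(drive)
}

month_index_rows <- function(df) df$year * 12 + (df$month - 1)

# One-month constant-field temperature series builder.
flat_temp_series <- function(months, lat, lon, value, scenario = "reference") {
  temperature_field_series(
    months, lat, lon,
    array(value, dim = c(nrow(months), length(lat), length(lon))),
    scenario = scenario)
}
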