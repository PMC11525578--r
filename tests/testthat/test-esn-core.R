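test_that("initialization honors the weight distribution and sparsity", {
  cfg <- esn_config(reservoir_size = 300L, seed = 5L)
  net <- init_esn(cfg, input_dim = 10L)
  expect_true(all(net$W_in >= -0.5 & net$W_in <= 0.5))
  expect_equal(dim(net$W_in), c(300L, 11L))
  expect_equal(dim(net$W), c(300L, 300L))
  # zero fraction within 3 binomial SDs of 1 - c = 0.5
  zero_frac <- mean(net$W == 0)
  expect_lt(abs(zero_frac - 0.5), 3 * sqrt(0.25 / 300^2))  # 3 binomial SDs
  expect_null(net$W_out)
})

test_that("recurrent matrix is rescaled to the target spectral radius (dense oracle)", {
  cfg <- esn_config(reservoir_size = 150L, spectral_radius = 1.25, seed = 2L)
  net <- init_esn(cfg, input_dim = 4L)
  rho <- max(Mod(eigen(net$W, only.values = TRUE)$values))
  expect_equal(rho, 1.25, tolerance = 1e-6)

  cfg2 <- esn_config(reservoir_size = 150L, spectral_radius = 0.8, seed = 2L)
  net2 <- init_esn(cfg2, input_dim = 4L)
  rho2 <- max(Mod(eigen(net2$W, only.values = TRUE)$values))
  expect_equal(rho2, 0.8, tolerance = 1e-6)
})

test_that("iterative spectral radius agrees with the dense eigendecomposition", {
  set.seed(8)
  for (n in c(120L, 250L)) {
    w <- matrix(runif(n * n, -0.5, 0.5) * (runif(n * n) < 0.5), n, n)
    expect_equal(spectral_radius(w),
                 max(Mod(eigen(w, only.values = TRUE)$values)),
                 tolerance = 1e-9)
  }
})

test_that("zero connectivity gives a zero reservoir with a warning", {
  cfg <- esn_config(reservoir_size = 50L, connectivity = 0, seed = 1L)
  expect_warning(net <- init_esn(cfg, input_dim = 3L), "all-zero")
  expect_true(all(net$W == 0))
})

test_that("initialization is bit-identical for identical config and seed", {
  cfg <- esn_config(reservoir_size = 120L, seed = 99L)
  a <- init_esn(cfg, 6L)
  b <- init_esn(cfg, 6L)
  expect_identical(a$W_in, b$W_in)
  expect_identical(a$W, b$W)
})

test_that("config validation rejects out-of-range hyperparameters", {
  expect_error(esn_config(reservoir_size = 0), "reservoir_size")
  expect_error(esn_config(alpha = 0), "alpha")
  expect_error(esn_config(alpha = 1.2), "alpha")
  expect_error(esn_config(connectivity = 1.5), "connectivity")
  expect_error(esn_config(ridge_lambda = -1), "ridge_lambda")
})

test_that("state update follows the leaky-integrator recursion exactly", {
  # alpha = 1, all-zero weights: x_n = tanh(0) = 0
  net0 <- toy_esn(matrix(0, 3, 3), matrix(0, 3, 3), alpha = 1)
  expect_equal(update_state(net0, c(0.3, -0.2, 0.9), c(0.1, 0.7)), rep(0, 3))

  # alpha = 1: the leak term vanishes
  set.seed(21)
  w_in <- matrix(runif(3 * 3, -0.5, 0.5), 3, 3)
  w <- matrix(runif(9, -0.5, 0.5), 3, 3)
  net <- toy_esn(w_in, w, alpha = 1)
  x <- c(0.2, -0.4, 0.1); u <- c(0.5, 0.9)
  expect_equal(update_state(net, x, u),
               as.vector(tanh(w_in %*% c(1, u) + w %*% x)), tolerance = 1e-15)

  # two steps against the scalar-loop oracle at alpha = 0.5
  net5 <- toy_esn(w_in, w, alpha = 0.5)
  x1 <- update_state(net5, x, u)
  x2 <- update_state(net5, x1, rev(u))
  o1 <- oracle_update(w_in, w, x, u, 0.5)
  o2 <- oracle_update(w_in, w, o1, rev(u), 0.5)
  expect_equal(x1, o1, tolerance = 1e-12)
  expect_equal(x2, o2, tolerance = 1e-12)

  expect_error(update_state(net5, c(1, 2), u), "reservoir size")
  expect_error(update_state(net5, x, c(1, 2, 3)), "W_in")
})

test_that("run_reservoir batches the recursion without resetting state", {
  set.seed(3)
  w_in <- matrix(runif(4 * 3, -0.5, 0.5), 4, 3)
  w <- matrix(runif(16, -0.5, 0.5), 4, 4)
  net <- toy_esn(w_in, w, alpha = 0.7)
  u <- matrix(runif(2 * 9, 0, 1), 2, 9)

  states <- run_reservoir(net, u)
  # single input equals one update from zero
  expect_equal(run_reservoir(net, u[, 1, drop = FALSE])[, 1],
               update_state(net, numeric(4), u[, 1]))
  # step-by-step oracle
  x <- numeric(4)
  for (t in 1:9) {
    x <- oracle_update(w_in, w, x, u[, t], 0.7)
    expect_equal(states[, t], x, tolerance = 1e-12)
  }
  # splitting and chaining the final state equals one pass
  s1 <- run_reservoir(net, u[, 1:4])
  s2 <- run_reservoir(net, u[, 5:9], x0 = s1[, 4])
  expect_equal(cbind(s1, s2), states, tolerance = 1e-14)
  expect_error(run_reservoir(net, u[, 0]), "empty")
})

test_that("ridge readout matches the explicit normal-equation solution", {
  set.seed(14)
  # small dense problem, features < samples (primal path)
  w_in <- matrix(runif(3 * 3, -0.5, 0.5), 3, 3)
  w <- matrix(runif(9, -0.5, 0.5), 3, 3)
  net <- toy_esn(w_in, w, alpha = 0.9, lambda = 1e-2, washout = 0L)
  u <- matrix(runif(2 * 12), 2, 12)
  states <- run_reservoir(net, u)
  y <- rnorm(12)
  for (lambda in c(1e-8, 1e-2)) {
    trained <- train_readout(net, u, states, y, lambda = lambda)
    d <- t(rbind(1, u, states))
    oracle <- solve(crossprod(d) + lambda * diag(ncol(d)), crossprod(d, y))
    expect_equal(as.vector(trained$W_out), as.vector(oracle), tolerance = 1e-8)
  }
})

test_that("primal and dual ridge formulations agree when features exceed samples", {
  set.seed(15)
  # features (1 + K + N = 26) > samples (8): package takes the dual path
  w_in <- matrix(runif(20 * 6, -0.5, 0.5), 20, 6)
  w <- 0.5 * matrix(runif(400, -0.5, 0.5), 20, 20)
  net <- toy_esn(w_in, w, alpha = 0.8)
  u <- matrix(runif(5 * 8), 5, 8)
  states <- run_reservoir(net, u)
  y <- rnorm(8)
  for (lambda in c(1e-8, 1e-2)) {
    trained <- train_readout(net, u, states, y, lambda = lambda)
    d <- t(rbind(1, u, states))
    primal <- solve(crossprod(d) + lambda * diag(ncol(d)), crossprod(d, y))
    expect_equal(as.vector(trained$W_out), as.vector(primal), tolerance = 1e-6)
  }
})

test_that("zero targets give a zero readout and washout bounds are checked", {
  set.seed(16)
  w_in <- matrix(runif(6 * 3, -0.5, 0.5), 6, 3)
  w <- 0.4 * matrix(runif(36, -0.5, 0.5), 6, 6)
  net <- toy_esn(w_in, w)
  u <- matrix(runif(2 * 10), 2, 10)
  states <- run_reservoir(net, u)
  trained <- train_readout(net, u, states, rep(0, 10), lambda = 1e-6)
  expect_equal(max(abs(trained$W_out)), 0, tolerance = 1e-12)
  expect_error(train_readout(net, u, states, rnorm(10), lambda = -1), "lambda")
  expect_error(train_readout(net, u, states, rnorm(10), washout = 10), "washout")
})

test_that("prediction applies the trained readout to [1; u; x]", {
  set.seed(17)
  w_in <- matrix(runif(5 * 4, -0.5, 0.5), 5, 4)
  w <- 0.5 * matrix(runif(25, -0.5, 0.5), 5, 5)
  net <- toy_esn(w_in, w, alpha = 0.6)
  u <- matrix(runif(3 * 7), 3, 7)
  expect_error(predict(net, u), "untrained")

  states <- run_reservoir(net, u)
  y <- rnorm(7)
  trained <- train_readout(net, u, states, y, lambda = 1e-4)
  pred <- predict(trained, u)
  # hand evaluation of the output equation
  for (t in 1:7) {
    expect_equal(pred[t],
                 as.vector(trained$W_out %*% c(1, u[, t], states[, t])),
                 tolerance = 1e-12)
  }
  # zero readout predicts zero
  trained$W_out[] <- 0
  expect_equal(as.vector(predict(trained, u)), rep(0, 7))
})

test_that("an overparameterized network interpolates its training targets", {
  cfg <- esn_config(reservoir_size = 200L, spectral_radius = 0.9,
                    ridge_lambda = 1e-12, washout = 2L, seed = 31L)
  net <- init_esn(cfg, input_dim = 3L)
  set.seed(31)
  u <- matrix(runif(3 * 20), 3, 20)
  y <- rnorm(20, mean = 90, sd = 5)
  states <- run_reservoir(net, u)
  trained <- train_readout(net, u, states, y)
  pred <- predict(trained, u)
  expect_lt(max(abs(pred[3:20] - y[3:20])), 1e-5)
})

test_that("rms error and its relative form follow their definitions", {
  expect_equal(rms_error(c(1, 2, 3), c(1, 2, 3))$rms, 0)
  e <- rms_error(c(3, 4), c(0, 0))
  expect_equal(e$rms, sqrt(12.5))
  t0 <- c(80, 100)
  e2 <- rms_error(t0 + c(3, -4), t0)
  expect_equal(e2$rms_relative, sqrt(12.5) / 90 * 100)
  expect_error(rms_error(numeric(0), numeric(0)), "length")
  expect_error(rms_error(1:3, 1:2), "length")
})

test_that("sub-unit spectral radius yields fading memory", {
  cfg <- esn_config(reservoir_size = 150L, spectral_radius = 0.8,
                    alpha = 1, seed = 77L)
  net <- init_esn(cfg, input_dim = 5L)
  set.seed(77)
  u <- matrix(runif(5 * 50), 5, 50)
  xa <- run_reservoir(net, u, x0 = runif(150, -1, 1))
  xb <- run_reservoir(net, u, x0 = runif(150, -1, 1))
  gap <- sqrt(colSums((xa - xb)^2))
  expect_lt(gap[50], 1e-6)
  expect_lt(gap[50], gap[1])
})

test_that("outputs vary continuously with the leakage parameter", {
  set.seed(19)
  w_in <- matrix(runif(6 * 3, -0.5, 0.5), 6, 3)
  w <- 0.6 * matrix(runif(36, -0.5, 0.5), 6, 6)
  u <- matrix(runif(2 * 15), 2, 15)
  y <- rnorm(15)
  out_for <- function(alpha) {
    net <- toy_esn(w_in, w, alpha = alpha)
    states <- run_reservoir(net, u)
    predict(train_readout(net, u, states, y, lambda = 1e-2), u)
  }
  a <- out_for(0.5)
  b <- out_for(0.5 + 1e-6)
  expect_lt(max(abs(a - b)), 1e-4)
})

test_that("network archives round-trip through disk", {
  cfg <- esn_config(reservoir_size = 40L, seed = 4L)
  net <- init_esn(cfg, input_dim = 3L)
  u <- matrix(runif(3 * 12), 3, 12)
  states <- run_reservoir(net, u)
  net <- train_readout(net, u, states, rnorm(12), washout = 2L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_esn(net, path, lat = c(50, 51), lon = c(8, 9, 10))
  back <- load_esn(path)
  expect_identical(back$W_in, net$W_in)
  expect_identical(back$W_out, net$W_out)
  expect_equal(attr(back, "lat"), c(50, 51))
  expect_equal(as.vector(predict(back, u)), as.vector(predict(net, u)))
})
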