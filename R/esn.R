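#' Echo state network hyperparameters
#'
#' The reservoir-computing hyperparameters: reservoir size N, leakage alpha,
#' spectral radius of the recurrent matrix, reservoir connectivity, ridge
#' penalty of the readout regression, and the washout (initial months
#' excluded from readout fitting). Defaults are the study configuration:
#' N = 9000, alpha = 0.5, spectral radius 1.25, connectivity 0.5,
#' lambda = 1e-8.
#'
#' @param reservoir_size number of reservoir nodes N (>= 1).
#' @param alpha leakage parameter in (0, 1]: the fraction of each state
#'   update contributed by the new nonlinear drive.
#' @param spectral_radius target largest absolute eigenvalue of the recurrent
#'   matrix after rescaling; > 0. Note that values above 1 (as used here) do
#'   not satisfy the classical sufficient condition for the echo-state
#'   property; the tanh saturation keeps states bounded regardless.
#' @param connectivity fraction c in \[0, 1\] of recurrent weights retained;
#'   each entry is independently zeroed with probability 1 - c.
#' @param ridge_lambda ridge penalty lambda >= 0 of the readout regression.
#' @param washout number of initial time steps discarded before fitting the
#'   readout (>= 0); suppresses the x0 = 0 transient.
#' @param seed integer seed for the random input and recurrent weights.
#' @return an object of class `esn_config`.
#' @export
esn_config <- function(reservoir_size = 9000L, alpha = 0.5,
                       spectral_radius = 1.25, connectivity = 0.5,
                       ridge_lambda = 1e-8, washout = 6L, seed = 1L) {
  if (reservoir_size < 1) stop("reservoir_size must be >= 1", call. = FALSE)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  if (!(connectivity >= 0 && connectivity <= 1)) {
    stop("connectivity must be in [0, 1]", call. = FALSE)
  }
  if (ridge_lambda < 0) stop("ridge_lambda must be >= 0", call. = FALSE)
  if (spectral_radius < 0) stop("spectral_radius must be >= 0", call. = FALSE)
  if (washout < 0) stop("washout must be >= 0", call. = FALSE)
  structure(list(reservoir_size = as.integer(reservoir_size), alpha = alpha,
                 spectral_radius = spectral_radius, connectivity = connectivity,
                 ridge_lambda = ridge_lambda, washout = as.integer(washout),
                 seed = as.integer(seed)),
            class = "esn_config")
}

#' Initialize an echo state network
#'
#' Draws the fixed random weights: the input matrix `W_in` (N x (1+K)) from
#' the uniform distribution on \[-0.5, 0.5\], and the recurrent matrix `W`
#' (N x N) by the same procedure with each entry independently set to zero
#' with probability `1 - connectivity`, then rescaled so that its spectral
#' radius equals `spectral_radius`. These weights remain fixed; only the
#' linear readout is trained later.
#'
#' @param config an [esn_config()].
#' @param input_dim K, the length of one flattened input vector.
#' @return an object of class `esn` with elements `config`, `input_dim`,
#'   `W_in`, `W`, and `W_out` (`NULL` until [train_readout()]).
#' @export
init_esn <- function(config, input_dim) {
  stopifnot(inherits(config, "esn_config"))
  input_dim <- as.integer(input_dim)
  if (input_dim < 1L) stop("input_dim must be >= 1", call. = FALSE)
  n <- config$reservoir_size
  old_seed <- local_rng(config$seed)
  on.exit(restore_rng(old_seed), add = TRUE)

  w_in <- matrix(stats::runif(n * (1L + input_dim), -0.5, 0.5),
                 nrow = n, ncol = 1L + input_dim)
  w <- matrix(stats::runif(n * n, -0.5, 0.5), n, n)
  mask <- matrix(stats::runif(n * n) < config$connectivity, n, n)
  w <- w * mask
  rho <- spectral_radius(w)
  if (rho == 0) {
    if (config$connectivity == 0 || all(w == 0)) {
      warning("recurrent matrix is all-zero; spectral-radius rescaling skipped",
              call. = FALSE)
    } else {
      stop("recurrent matrix has zero spectral radius; cannot rescale", call. = FALSE)
    }
  } else {
    w <- w * (config$spectral_radius / rho)
  }
  structure(list(config = config, input_dim = input_dim,
                 W_in = w_in, W = w, W_out = NULL),
            class = "esn")
}

#' @export
print.esn <- function(x, ...) {
  cat(sprintf("<esn> N = %d, K = %d, alpha = %g, r_s = %g, c = %g, lambda = %g, %s\n",
              x$config$reservoir_size, x$input_dim, x$config$alpha,
              x$config$spectral_radius, x$config$connectivity,
              x$config$ridge_lambda,
              if (is.null(x$W_out)) "untrained" else "trained"))
  invisible(x)
}

#' Spectral radius of a square matrix
#'
#' Largest eigenvalue magnitude, via a sparse iterative eigensolver for
#' large matrices and a dense eigendecomposition for small ones.
#'
#' @param w square numeric matrix.
#' @return nonnegative scalar.
#' @export
spectral_radius <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (all(w == 0)) return(0)
  n <- nrow(w)
  if (n <= 100L) return(max(Mod(eigen(w, only.values = TRUE)$values)))
  ev <- tryCatch(
    RSpectra::eigs(w, k = 3L, which = "LM",
                   opts = list(retvec = FALSE, tol = 1e-12))$values,
    error = function(e) NULL)
  if (is.null(ev) || length(ev) == 0L) {
    return(max(Mod(eigen(w, only.values = TRUE)$values)))
  }
  max(Mod(ev))
}

#' Leaky-integrator reservoir state update
#'
#' One step of the state recursion
#' `x_n = (1 - alpha) * x_{n-1} + alpha * tanh(W_in [1; u_n] + W x_{n-1})`,
#' where `[1; u]` is the vertical concatenation of the constant bias 1 and
#' the input vector.
#'
#' @param esn an initialized [init_esn()] object.
#' @param x previous state vector of length N (`x_{n-1}`).
#' @param u input vector of length K for this step.
#' @param alpha leakage; defaults to the network's configured value.
#' @return the new state vector `x_n`.
#' @export
update_state <- function(esn, x, u, alpha = esn$config$alpha) {
  n <- esn$config$reservoir_size
  if (length(x) != n) {
    stop(sprintf("state length %d does not match reservoir size %d (W is %d x %d)",
                 length(x), n, n, n), call. = FALSE)
  }
  if (length(u) != esn$input_dim) {
    stop(sprintf("input length %d does not match W_in, which expects K = %d",
                 length(u), esn$input_dim), call. = FALSE)
  }
  drive <- esn$W_in %*% c(1, u) + esn$W %*% x
  as.vector((1 - alpha) * x + alpha * tanh(drive))
}

#' Run the reservoir over an input sequence
#'
#' Iterates [update_state()] over the columns of `inputs` without resetting
#' between steps; column t of the result holds the state after consuming
#' input t. Splitting a sequence and chaining the final state is identical
#' to a single pass.
#'
#' @param esn an initialized [init_esn()] object.
#' @param inputs `K x T` input matrix (columns = time steps), as produced by
#'   [flatten_inputs()].
#' @param x0 initial state; default all zeros.
#' @return `N x T` activation matrix.
#' @export
run_reservoir <- function(esn, inputs, x0 = NULL) {
  stopifnot(inherits(esn, "esn"))
  inputs <- as.matrix(inputs)
  tdim <- ncol(inputs)
  if (tdim == 0L) stop("empty input sequence", call. = FALSE)
  if (nrow(inputs) != esn$input_dim) {
    stop(sprintf("input rows (%d) do not match W_in input dimension K = %d",
                 nrow(inputs), esn$input_dim), call. = FALSE)
  }
  n <- esn$config$reservoir_size
  if (is.null(x0)) x0 <- numeric(n)
  alpha <- esn$config$alpha
  # batch the input contribution; the recurrent term must stay sequential
  drive_in <- esn$W_in %*% rbind(1, inputs)
  x <- as.vector(x0)
  states <- matrix(NA_real_, nrow = n, ncol = tdim)
  for (t in seq_len(tdim)) {
    x <- (1 - alpha) * x + alpha * tanh(drive_in[, t] + as.vector(esn$W %*% x))
    states[, t] <- x
  }
  states
}

#' Fit the linear readout by ridge regression
#'
#' Solves `argmin_Wout sum_t || y_t - Wout d_t ||^2 + lambda ||Wout||^2` in
#' closed form, with design vectors `d_t = [1; u_t; x_t]` and `t` restricted
#' to steps after the washout. Because the feature dimension 1 + K + N
#' usually far exceeds the number of monthly samples, the solver uses
#' whichever normal-equation formulation has the smaller linear system:
#' the feature-space (primal) system when features <= samples, otherwise the
#' sample-space (dual) system `Wout = (D' a)',  a = (D D' + lambda I)^{-1} y`.
#'
#' @param esn an initialized [init_esn()] object.
#' @param inputs `K x T` input matrix used to drive the reservoir.
#' @param activations `N x T` state matrix from [run_reservoir()] on the same
#'   inputs.
#' @param targets numeric target vector of length T (mortality rate,
#'   per 100,000/month), aligned with the input columns.
#' @param lambda ridge penalty; defaults to the configured value.
#' @param washout steps excluded from the fit; defaults to the configured
#'   value. `T - washout` must be >= 1.
#' @return the `esn` with `W_out` set (a `1 x (1 + K + N)` matrix).
#' @export
train_readout <- function(esn, inputs, activations, targets,
                          lambda = esn$config$ridge_lambda,
                          washout = esn$config$washout) {
  stopifnot(inherits(esn, "esn"))
  inputs <- as.matrix(inputs); activations <- as.matrix(activations)
  tdim <- ncol(inputs)
  if (ncol(activations) != tdim || length(targets) != tdim) {
    stop("inputs, activations and targets must align in time", call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (washout >= tdim) {
    stop("washout leaves no samples for the readout fit", call. = FALSE)
  }
  keep <- seq.int(washout + 1L, tdim)
  d <- t(rbind(1, inputs[, keep, drop = FALSE], activations[, keep, drop = FALSE]))
  y <- targets[keep]
  esn$W_out <- matrix(ridge_solve(d, y, lambda), nrow = 1L)
  esn
}

# Closed-form ridge solution choosing the smaller linear system.
# d: samples x features; y: samples. Returns the feature-length coefficient
# vector. Falls back to a pseudo-inverse with a warning when the chosen
# system is numerically singular (e.g. lambda = 0 with a degenerate design).
ridge_solve <- function(d, y, lambda) {
  n_s <- nrow(d); n_f <- ncol(d)
  if (n_f <= n_s) {
    a <- crossprod(d) + lambda * diag(n_f)
    b <- crossprod(d, y)
    tryCatch(as.vector(solve(a, b)),
             error = function(e) {
               warning("degenerate readout design; using pseudo-inverse",
                       call. = FALSE)
               as.vector(MASS::ginv(a) %*% b)
             })
  } else {
    g <- tcrossprod(d) + lambda * diag(n_s)
    a <- tryCatch(solve(g, y),
                  error = function(e) {
                    warning("degenerate readout design; using pseudo-inverse",
                            call. = FALSE)
                    as.vector(MASS::ginv(g) %*% y)
                  })
    as.vector(crossprod(d, a))
  }
}

#' Predict mortality rates from new inputs
#'
#' Drives the reservoir over the input sequence from `x0` and applies the
#' trained readout at every step: `y_n = W_out [1; u_n; x_n]`, so each output
#' reflects both the reservoir state and the current input directly.
#'
#' @param object a trained `esn` (after [train_readout()]).
#' @param inputs `K x T` input matrix in the same flattening order as
#'   training.
#' @param x0 initial reservoir state; default all zeros. Pass the final
#'   training state to continue a contiguous stream.
#' @param ... unused.
#' @return numeric vector of T predicted rates, with attribute
#'   `"final_state"` holding the last reservoir state.
#' @export
predict.esn <- function(object, inputs, x0 = NULL, ...) {
  if (is.null(object$W_out)) {
    stop("network is untrained: call train_readout() first", call. = FALSE)
  }
  states <- run_reservoir(object, inputs, x0 = x0)
  inputs <- as.matrix(inputs)
  y <- as.vector(object$W_out %*% rbind(1, inputs, states))
  attr(y, "final_state") <- states[, ncol(states)]
  y
}

#' Root-mean-square prediction error
#'
#' `rms = sqrt(mean((pred - target)^2))` and its value relative to the mean
#' target, in percent.
#'
#' @param pred,target numeric vectors of equal, positive length.
#' @return list of class `esn_error` with elements `rms` and `rms_relative`
#'   (percent of the mean target).
#' @export
rms_error <- function(pred, target) {
  if (length(pred) == 0L || length(pred) != length(target)) {
    stop("pred and target must have equal, nonzero length", call. = FALSE)
  }
  rms <- sqrt(mean((pred - target)^2))
  structure(list(rms = rms, rms_relative = rms / mean(target) * 100),
            class = "esn_error")
}

#' @export
print.esn_error <- function(x, ...) {
  cat(sprintf("RMS error %.4g (%.2f%% of mean target)\n", x$rms, x$rms_relative))
  invisible(x)
}

#' Serialize a trained network to disk
#'
#' Writes weights, configuration, input dimension and the flattening-order
#' axes to a single archive (RDS, schema version 1). [load_esn()] restores
#' it and checks the schema.
#'
#' @param esn an `esn` object.
#' @param path file path.
#' @param lat,lon optional grid axes recording the flattening order the
#'   network was trained with.
#' @return `path`, invisibly.
#' @export
save_esn <- function(esn, path, lat = NULL, lon = NULL) {
  stopifnot(inherits(esn, "esn"))
  obj <- list(schema = "esnmort/esn", schema_version = 1L,
              config = esn$config, input_dim = esn$input_dim,
              W_in = esn$W_in, W = esn$W, W_out = esn$W_out,
              lat = lat, lon = lon)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_esn
#' @export
load_esn <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "esnmort/esn")) {
    stop("not an esnmort network archive", call. = FALSE)
  }
  esn <- structure(list(config = obj$config, input_dim = obj$input_dim,
                        W_in = obj$W_in, W = obj$W, W_out = obj$W_out),
                   class = "esn")
  attr(esn, "lat") <- obj$lat
  attr(esn, "lon") <- obj$lon
  esn
}
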