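# Leaky echo state network: construction, state propagation, ridge readout
# and prediction. The reservoir (sparse random connectivity C, dense input
# weights F) is fixed at construction; only the 1 x N readout W is learned.

#' Echo state network configuration
#'
#' Defaults follow the reference parameterization: N = 1000 nodes,
#' spectral radius 0.5, input-weight magnitudes uniform on \[0.1, 0.5\],
#' tau = 1 step, leak gamma = 0.5 and state-noise scale 1e-4 during
#' learning (noise is switched off for prediction). The connectivity
#' density (5%) and the ridge penalty (0, i.e. pure pseudo-inverse with
#' the state noise acting as the regularizer) are conventional choices.
#'
#' @param n_nodes reservoir size N.
#' @param spectral_radius magnitude of the leading eigenvalue of C.
#' @param density fraction of nonzero entries of C, in (0, 1].
#' @param input_weight_low,input_weight_high input-weight magnitude range.
#' @param input_sign_symmetric if `TRUE` (default) input weights get a
#'   random sign, giving a zero-mean drive; `FALSE` keeps them all
#'   positive (the literal reading of a magnitude interval).
#' @param tau time constant in samples.
#' @param gamma leak rate in (0, 1].
#' @param noise_scale uniform state-noise amplitude during learning.
#' @param ridge_lambda ridge penalty for the readout (>= 0; 0 requests the
#'   minimum-norm pseudo-inverse solution). The default 10 is a weak
#'   penalty, about 1e-3 relative to the state covariance scale of a
#'   typical training set; pure pseudo-inversion lets the readout exploit
#'   noise-dominated state directions, which shows up as baseline jitter
#'   in the predicted swing phase and wrecks foot-off thresholding (see
#'   the methods vignette).
#' @param seed integer seed; the network is fully determined by it.
#' @export
esn_config <- function(n_nodes = 1000, spectral_radius = 0.5, density = 0.05,
                       input_weight_low = 0.1, input_weight_high = 0.5,
                       input_sign_symmetric = TRUE, tau = 1, gamma = 0.5,
                       noise_scale = 1e-4, ridge_lambda = 10, seed = 1L) {
  stopifnot(n_nodes >= 1, spectral_radius > 0, density > 0, density <= 1,
            gamma > 0, gamma <= 1, tau > 0, noise_scale >= 0,
            ridge_lambda >= 0,
            input_weight_low >= 0, input_weight_high >= input_weight_low)
  structure(list(n_nodes = as.integer(n_nodes),
                 spectral_radius = spectral_radius, density = density,
                 input_weight_low = input_weight_low,
                 input_weight_high = input_weight_high,
                 input_sign_symmetric = isTRUE(input_sign_symmetric),
                 tau = tau, gamma = gamma, noise_scale = noise_scale,
                 ridge_lambda = ridge_lambda, seed = as.integer(seed)),
            class = "esn_config")
}

# evaluate code under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit sub-seed derivation
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k) %% 2147483647)
}

#' Initialize an echo state network
#'
#' Draws a sparse random connectivity matrix (nonzero positions
#' Bernoulli(density), values uniform on (-1, 1)) and rescales it so the
#' magnitude of its leading eigenvalue equals the requested spectral
#' radius. Input weights are dense with magnitudes uniform on
#' `[input_weight_low, input_weight_high]` and, by default, random signs.
#' Everything is determined by `config$seed`.
#'
#' @param config an [esn_config()].
#' @param n_inputs number of input rows K (default 3: a_bar, v_bar, p_bar).
#' @return object of class `echo_state_network` with fields `C` (sparse
#'   N x N), `F_in` (N x K), `W` (`NULL` until trained) and `config`.
#' @export
init_network <- function(config = esn_config(), n_inputs = 3L) {
  N <- config$n_nodes
  draw <- function() {
    nz <- which(stats::runif(as.numeric(N) * N) < config$density)
    if (!length(nz)) return(NULL)
    C <- Matrix::sparseMatrix(i = ((nz - 1) %% N) + 1,
                              j = ((nz - 1) %/% N) + 1,
                              x = stats::runif(length(nz), -1, 1),
                              dims = c(N, N))
    rho <- spectral_radius_of(C)
    if (rho <= 0) return(NULL)
    C * (config$spectral_radius / rho)
  }
  with_seed(config$seed, {
    C <- draw()
    if (is.null(C)) C <- draw()
    if (is.null(C)) stop("degenerate reservoir")
    mag <- stats::runif(N * n_inputs, config$input_weight_low,
                        config$input_weight_high)
    if (config$input_sign_symmetric) {
      mag <- mag * sample(c(-1, 1), N * n_inputs, replace = TRUE)
    }
    F_in <- matrix(mag, nrow = N, ncol = n_inputs)
    structure(list(C = C, F_in = F_in, W = NULL, config = config,
                   n_inputs = n_inputs),
              class = "echo_state_network")
  })
}

# |leading eigenvalue| of a (sparse) square matrix
spectral_radius_of <- function(C) {
  ev <- eigen(as.matrix(C), only.values = TRUE)$values
  max(Mod(ev))
}

#' @export
print.echo_state_network <- function(x, ...) {
  cat(sprintf("<echo_state_network> N = %d, spectral radius = %g, density = %g, %s\n",
              x$config$n_nodes, x$config$spectral_radius, x$config$density,
              if (is.null(x$W)) "untrained" else "trained"))
  invisible(x)
}

#' Propagate reservoir states for one input sequence
#'
#' Explicit Euler discretization (dt = 1 sample) of the leaky tanh
#' reservoir dynamics; see [esn_config()] for the parameters. State noise
#' (uniform, scale `noise_scale`) is added only when `noise_on = TRUE`
#' (training); it is switched off for prediction.
#'
#' @param esn an [init_network()] result.
#' @param x input: a `network_input` or a K x T matrix.
#' @param q0 initial state (default zeros).
#' @param noise_on logical.
#' @return N x T matrix of reservoir states (all T states, no washout).
#' @export
run_states <- function(esn, x, q0 = NULL, noise_on = FALSE) {
  stopifnot(inherits(esn, "echo_state_network"))
  if (inherits(x, "network_input")) x <- x$x
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (nrow(x) != esn$n_inputs) {
    stop(sprintf("input must have %d rows", esn$n_inputs))
  }
  N <- esn$config$n_nodes
  if (is.null(q0)) q0 <- numeric(N)
  stopifnot(length(q0) == N)
  eps <- if (noise_on) esn$config$noise_scale else 0
  C <- methods::as(esn$C, "CsparseMatrix")
  esn_run_states_cpp(C@p, C@i, C@x, esn$F_in, x, as.numeric(q0),
                     esn$config$gamma, esn$config$tau, eps)
}

#' Fit the linear readout by (ridge) least squares
#'
#' Concatenates the usable state columns of all training series and solves
#' `min ||z - W Q||^2 + lambda ||W||^2`. With `lambda = 0` the
#' minimum-norm pseudo-inverse solution is returned (`W = z Q^+`, computed
#' through the Gram matrix `Q Q'`); with `lambda > 0` the regularized
#' normal equations `(Q Q' + lambda I) W' = Q z'` are solved.
#'
#' @param states list of N x T_i state matrices (one per training series).
#' @param targets list of length-T_i target vectors.
#' @param masks optional list of logical vectors; `FALSE` columns
#'   (transients) are dropped. `NULL` keeps everything.
#' @param lambda ridge penalty (>= 0).
#' @return list with `W` (1 x N readout), `residual_rms` (training RMS on
#'   the usable columns) and `n_columns` used.
#' @export
fit_readout <- function(states, targets, masks = NULL, lambda = 0) {
  stopifnot(is.list(states), is.list(targets),
            length(states) == length(targets), lambda >= 0)
  N <- nrow(states[[1]])
  G <- matrix(0, N, N)
  cvec <- numeric(N)
  ncol_tot <- 0L
  for (i in seq_along(states)) {
    Q <- states[[i]]
    z <- targets[[i]]
    if (ncol(Q) != length(z)) {
      stop(sprintf("series %d: state and target lengths differ", i))
    }
    if (!is.null(masks)) {
      m <- masks[[i]]
      stopifnot(length(m) == length(z))
      Q <- Q[, m, drop = FALSE]
      z <- z[m]
    }
    if (!ncol(Q)) next
    G <- G + tcrossprod(Q)
    cvec <- cvec + drop(Q %*% z)
    ncol_tot <- ncol_tot + ncol(Q)
  }
  if (ncol_tot == 0L) stop("no usable training columns")
  if (ncol_tot < N) {
    warning(sprintf("only %d usable columns for %d nodes; readout underdetermined",
                    ncol_tot, N))
  }
  if (lambda > 0) {
    w <- solve(G + diag(lambda, N), cvec)
  } else {
    # pseudo-inverse through the Gram matrix: z Q^+ = ((Q Q')^+ Q z')'
    e <- eigen(G, symmetric = TRUE)
    tol <- max(N, ncol_tot) * .Machine$double.eps * max(e$values, 0)
    keep <- e$values > tol
    w <- e$vectors[, keep, drop = FALSE] %*%
      ((crossprod(e$vectors[, keep, drop = FALSE], cvec)) / e$values[keep])
    w <- drop(w)
  }
  sse <- 0; ntot <- 0L
  for (i in seq_along(states)) {
    Q <- states[[i]]; z <- targets[[i]]
    if (!is.null(masks)) {
      m <- masks[[i]]
      Q <- Q[, m, drop = FALSE]; z <- z[m]
    }
    if (!ncol(Q)) next
    r <- z - drop(crossprod(Q, w))
    sse <- sse + sum(r^2)
    ntot <- ntot + length(r)
  }
  list(W = matrix(w, nrow = 1), residual_rms = sqrt(sse / ntot),
       n_columns = ncol_tot)
}

#' Attach a fitted readout to a network
#' @param esn an `echo_state_network`.
#' @param W 1 x N readout matrix (or length-N vector).
#' @export
set_readout <- function(esn, W) {
  if (is.vector(W)) W <- matrix(W, nrow = 1)
  stopifnot(ncol(W) == esn$config$n_nodes)
  esn$W <- W
  esn
}

#' Predict z-scored GRF from network input
#'
#' Runs the reservoir deterministically (noise off, `q0 = 0` by default)
#' and applies the trained readout: `y = W q`.
#'
#' @param esn a trained `echo_state_network`.
#' @param x `network_input` or K x T matrix.
#' @param q0 initial state (default zeros).
#' @return numeric vector of length T.
#' @export
predict_grf <- function(esn, x, q0 = NULL) {
  if (is.null(esn$W)) stop("readout not trained")
  Q <- run_states(esn, x, q0 = q0, noise_on = FALSE)
  drop(esn$W %*% Q)
}

#' Serialize / restore a trained network as JSON
#'
#' The archive stores the sparse connectivity in triplet form, the input
#' weights, the readout and the configuration, plus a format version.
#'
#' @param esn an `echo_state_network`.
#' @param path output file.
#' @export
save_network <- function(esn, path) {
  tri <- Matrix::summary(esn$C)
  obj <- list(format = "esngait-network", version = 1L,
              config = unclass(esn$config), n_inputs = esn$n_inputs,
              C_i = tri$i, C_j = tri$j, C_x = tri$x,
              F_in = as.numeric(esn$F_in),
              W = if (is.null(esn$W)) NULL else as.numeric(esn$W))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "esngait-network")) {
    stop("not an esngait network archive")
  }
  cfg <- do.call(esn_config, obj$config)
  N <- cfg$n_nodes
  C <- Matrix::sparseMatrix(i = obj$C_i, j = obj$C_j, x = obj$C_x,
                            dims = c(N, N))
  esn <- structure(list(C = C,
                        F_in = matrix(obj$F_in, nrow = N),
                        W = if (is.null(obj$W)) NULL else matrix(obj$W, nrow = 1),
                        config = cfg, n_inputs = ncol(matrix(obj$F_in, nrow = N))),
                   class = "echo_state_network")
  esn
}
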