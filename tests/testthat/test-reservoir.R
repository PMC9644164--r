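test_that("init_network is seeded, sparse and spectral-radius normalized", {
  cfg <- esn_config(n_nodes = 200, density = 0.05, seed = 11)
  esn <- init_network(cfg)
  esn2 <- init_network(cfg)
  expect_identical(as.matrix(esn$C), as.matrix(esn2$C))
  expect_identical(esn$F_in, esn2$F_in)

  rho <- max(Mod(eigen(as.matrix(esn$C), only.values = TRUE)$values))
  expect_lt(abs(rho - 0.5), 1e-9)

  # binomial-count oracle: nnz ~ Binomial(200^2, 0.05)
  nnz <- length(esn$C@x)
  expect_gte(nnz, 1600)
  expect_lte(nnz, 2400)

  mags <- abs(esn$F_in)
  expect_gte(min(mags), 0.1)
  expect_lte(max(mags), 0.5)
  expect_true(any(esn$F_in < 0))   # symmetric signs by default
  lit <- init_network(esn_config(n_nodes = 50, seed = 2,
                                 input_sign_symmetric = FALSE))
  expect_true(all(lit$F_in > 0))
})

test_that("spectral-radius normalization is exact across seeds", {
  for (seed in 1:5) {
    esn <- init_network(esn_config(n_nodes = 120, spectral_radius = 0.5,
                                   seed = seed))
    rho <- max(Mod(eigen(as.matrix(esn$C), only.values = TRUE)$values))
    expect_lt(abs(rho - 0.5), 1e-9)
  }
})

test_that("run_states follows the leaky Euler recursion", {
  # zero input, zero state: exact fixed point
  esn <- init_network(esn_config(n_nodes = 30, seed = 3))
  Q <- run_states(esn, matrix(0, 3, 50))
  expect_true(all(Q == 0))

  # hand recursion oracle, N = 1
  e1 <- init_network(esn_config(n_nodes = 1, density = 1, seed = 1))
  e1$C <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(1, 1))
  e1$F_in <- matrix(c(0.3, 0, 0), nrow = 1)
  Q1 <- run_states(e1, matrix(c(1, 0, 0, 1, 0, 0), nrow = 3))
  q1 <- tanh(0.3)
  expect_equal(Q1[1, 1], q1, tolerance = 1e-12)
  expect_equal(Q1[1, 2], 0.5 * q1 + tanh(0.3), tolerance = 1e-12)

  # determinism of the noise path under set.seed
  esn <- init_network(esn_config(n_nodes = 40, seed = 5))
  x <- matrix(runif(3 * 100, -1, 1), nrow = 3)
  set.seed(7); Qa <- run_states(esn, x, noise_on = TRUE)
  set.seed(7); Qb <- run_states(esn, x, noise_on = TRUE)
  expect_identical(Qa, Qb)
  expect_false(identical(Qa, run_states(esn, x, noise_on = FALSE)))
})

test_that("echo-state property: initial conditions are forgotten", {
  set.seed(1)
  esn <- init_network(esn_config(n_nodes = 150, seed = 8))
  x <- matrix(runif(3 * 400, -1, 1), nrow = 3)
  q0a <- runif(150, -1, 1)
  q0b <- runif(150, -1, 1)
  Qa <- run_states(esn, x, q0 = q0a)
  Qb <- run_states(esn, x, q0 = q0b)
  d <- sqrt(colSums((Qa - Qb)^2))
  d0 <- sqrt(sum((q0a - q0b)^2))
  expect_lt(d[400] / d0, 1e-6)
  expect_true(all(diff(d[10:400]) <= 1e-12))
})

test_that("fit_readout matches the normal-equation oracle", {
  set.seed(12)
  for (seed in 1:5) {
    Q <- matrix(rnorm(50 * 200), 50, 200)
    z <- rnorm(200)
    f <- fit_readout(list(Q), list(z), lambda = 0.1)
    W_ref <- t(solve(tcrossprod(Q) + 0.1 * diag(50), Q %*% z))
    expect_relative_equal(f$W, W_ref, 1e-8)
  }

  # representable target: residual at machine precision (lambda = 0)
  Q <- matrix(rnorm(20 * 300), 20, 300)
  z <- Q[7, ]
  f0 <- fit_readout(list(Q), list(z), lambda = 0)
  expect_lt(f0$residual_rms, 1e-8)

  # zero target
  fz <- fit_readout(list(Q), list(rep(0, 300)), lambda = 0.5)
  expect_lt(max(abs(fz$W)), 1e-12)

  # multi-series concatenation with masks equals manual concatenation
  Q1 <- matrix(rnorm(30 * 80), 30); Q2 <- matrix(rnorm(30 * 60), 30)
  z1 <- rnorm(80); z2 <- rnorm(60)
  m1 <- rep(c(FALSE, TRUE), c(10, 70)); m2 <- rep(TRUE, 60)
  f2 <- fit_readout(list(Q1, Q2), list(z1, z2), list(m1, m2), lambda = 0.2)
  Qc <- cbind(Q1[, m1], Q2)
  zc <- c(z1[m1], z2)
  W_ref <- t(solve(tcrossprod(Qc) + 0.2 * diag(30), Qc %*% zc))
  expect_relative_equal(f2$W, W_ref, 1e-8)

  expect_error(fit_readout(list(Q1), list(rnorm(79))), "lengths differ")
  expect_error(fit_readout(list(Q1), list(z1), list(rep(FALSE, 80))),
               "no usable")
})

test_that("predict_grf is deterministic and requires a readout", {
  esn <- init_network(esn_config(n_nodes = 60, seed = 4))
  x <- matrix(runif(3 * 120, -1, 1), nrow = 3)
  expect_error(predict_grf(esn, x), "readout not trained")
  esn <- set_readout(esn, rnorm(60))
  y1 <- predict_grf(esn, x)
  expect_identical(y1, predict_grf(esn, x))
  expect_length(y1, 120)
  expect_true(all(predict_grf(esn, matrix(0, 3, 10)) == 0))
})

test_that("network archives round-trip through JSON", {
  esn <- set_readout(init_network(esn_config(n_nodes = 40, seed = 9)),
                     rnorm(40))
  path <- withr::local_tempfile(fileext = ".json")
  save_network(esn, path)
  back <- load_network(path)
  expect_equal(as.matrix(back$C), as.matrix(esn$C), tolerance = 1e-12)
  expect_equal(back$F_in, esn$F_in, tolerance = 1e-12)
  expect_equal(back$W, esn$W, tolerance = 1e-12)
  x <- matrix(runif(3 * 50), nrow = 3)
  expect_equal(predict_grf(back, x), predict_grf(esn, x), tolerance = 1e-10)
})
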