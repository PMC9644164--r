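test_that("Butterworth design matches the reference coefficients", {
  # frozen oracle: scipy.signal.butter(2, 1, "highpass", fs=2000/14)
  ba <- butter_design(2, 1, 2000 / 14, "high")
  expect_relative_equal(ba$b, c(0.96937834471788481, -1.93875668943576962,
                                0.96937834471788481))
  expect_relative_equal(ba$a, c(1.0, -1.93781878374678360,
                                0.93969459512475820))
})

test_that("bidirectional high-pass removes DC, passes band, blocks stopband", {
  fs <- 2000 / 14
  t <- seq(0, 8, by = 1 / fs)
  sig <- function(v) sampled_signal(v, fs)
  interior <- 100:(length(t) - 100)

  out <- highpass_bidirectional(sig(rep(3.5, length(t))), 1, 2)
  expect_lt(max(abs(out$values[interior])), 1e-6 * 3.5)

  x10 <- sin(2 * pi * 10 * t)
  y10 <- drop(highpass_bidirectional(sig(x10), 1, 2)$values)
  expect_lt(abs(sd(y10[interior]) / sd(x10[interior]) - 1), 0.02)
  expect_equal(which.max(ccf(y10[interior], x10[interior], lag.max = 5,
                             plot = FALSE)$acf), 6)  # zero lag

  x01 <- sin(2 * pi * 0.1 * t)
  y01 <- drop(highpass_bidirectional(sig(x01), 1, 2)$values)
  expect_lt(max(abs(y01[interior])), 0.1)

  expect_error(highpass_bidirectional(sig(x10), cutoff = 80), "Nyquist")
})

test_that("resampling preserves DC and matches an analytic sine", {
  n <- 7000
  cst <- resample_grf(sampled_signal(rep(500, n), 1000), 1000 / 7)
  expect_equal(ncol(cst$values), 1000)               # ceiling(7000/7)
  expect_lt(max(abs(cst$values - 500)), 1e-9 * 500)

  s <- sin(2 * pi * 5 * (0:(n - 1)) / 1000)
  out <- resample_grf(sampled_signal(s, 1000), 1000 / 7)
  v <- drop(out$values)
  tn <- (seq_along(v) - 1) * 7 / 1000
  interior <- 20:(length(v) - 20)
  expect_lt(max(abs(v[interior] - sin(2 * pi * 5 * tn[interior]))), 1e-3)

  ident <- resample_grf(sampled_signal(s, 1000), 1000)
  expect_identical(drop(ident$values), s, ignore_attr = TRUE)
  expect_error(resample_grf(sampled_signal(s, 1000), 2000), "upsampling")
})

test_that("resampling preserves stance support duration on noise-free GRF", {
  tr <- synthesize_trial(
    synthetic_trial_spec(gait_pattern_spec("running"), n_strides = 20,
                         seed = 5), "t")
  rs <- resample_grf(tr$grf, tr$accel$fs)
  v <- drop(rs$values)
  gt <- tr$events
  for (i in 2:(length(gt$foot_contacts) - 1)) {
    a <- gt$foot_contacts[i]
    b <- gt$foot_offs[gt$foot_offs > a][1]
    inside <- v[(a + 1):(b - 2)]
    outside <- v[(b + 3):(gt$foot_contacts[i + 1] - 3)]
    expect_gt(min(inside), 0.01 * max(v))
    expect_lt(max(abs(outside)), 0.01 * max(v))
  }
})

test_that("PCA re-orientation matches eigen decomposition and is rotation invariant", {
  # all variance on one axis
  a <- sampled_signal(rbind(1:4, 0, 0), 10)
  expect_equal(drop(reorient_pca(a, "dominant-loading-positive")$values),
               c(-1.5, -0.5, 0.5, 1.5), ignore_attr = TRUE)

  set.seed(4)
  X <- matrix(rnorm(600), nrow = 3)
  s <- sampled_signal(X, 100)
  ah <- drop(reorient_pca(s)$values)
  # brute-force oracle
  Xc <- X - rowMeans(X)
  ev <- eigen(tcrossprod(Xc) / (ncol(X) - 1), symmetric = TRUE)
  ref <- drop(crossprod(ev$vectors[, 1], Xc))
  expect_lt(min(max(abs(ah - ref)), max(abs(ah + ref))), 1e-9)
  expect_equal(var(ah), ev$values[1], tolerance = 1e-12)

  # invariance under rotation of the sensor axes (up to global sign)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  ah2 <- drop(reorient_pca(sampled_signal(R %*% X, 100))$values)
  expect_lt(min(max(abs(ah2 - ah)), max(abs(ah2 + ah))), 1e-8)

  expect_error(reorient_pca(sampled_signal(matrix(1, 3, 10), 10)),
               "degenerate covariance")
})

test_that("cumulative integration matches analytic results", {
  z <- integrate_cumulative(sampled_signal(rep(0, 100), 100))
  expect_true(all(z$values == 0))

  one <- integrate_cumulative(sampled_signal(rep(1, 101), 100))
  expect_equal(drop(one$values)[101], 1, tolerance = 1e-9)

  fs <- 1000
  t <- (0:2000) / fs
  x <- cos(2 * pi * 10 * t)
  y <- drop(integrate_cumulative(sampled_signal(x, fs))$values)
  ref <- sin(2 * pi * 10 * t) / (2 * pi * 10)
  expect_lt(max(abs(y - ref)), 1e-3 * max(abs(ref)))
})

test_that("range normalization and z-scoring follow their conventions", {
  # division by the range (max - min = 4), so the output range is 1
  expect_equal(drop(range_normalize(sampled_signal(c(0, 2, 4), 10))$values),
               c(0, 0.5, 1), ignore_attr = TRUE)
  set.seed(2)
  v <- rnorm(500)
  rn <- drop(range_normalize(sampled_signal(v, 10))$values)
  expect_equal(max(rn) - min(rn), 1, tolerance = 1e-12)
  expect_error(range_normalize(sampled_signal(rep(2, 5), 10)), "zero range")

  expect_equal(drop(zscore_signal(sampled_signal(c(1, 2, 3), 10))$values),
               c(-1, 0, 1), ignore_attr = TRUE)   # sample-sd convention
  zs <- drop(zscore_signal(sampled_signal(v, 10))$values)
  expect_lt(abs(mean(zs)), 1e-12)
  expect_lt(abs(sd(zs) - 1), 1e-12)
  zs2 <- drop(zscore_signal(sampled_signal(zs, 10))$values)
  expect_equal(zs2, zs, tolerance = 1e-12)
  expect_error(zscore_signal(sampled_signal(rep(1, 5), 10)), "constant")
})

test_that("build_input yields range-1 rows and is scale/rotation invariant", {
  tr <- tiny_cohort(n_per_mode = 1, n_strides = 10, seed = 9)[[1]]
  x <- build_input(tr$accel)$x
  expect_equal(dim(x)[1], 3)
  expect_equal(apply(x, 1, function(r) max(r) - min(r)), rep(1, 3),
               tolerance = 1e-9, ignore_attr = TRUE)

  doubled <- tr$accel
  doubled$values <- doubled$values * 2
  expect_equal(build_input(doubled)$x, x, tolerance = 1e-8)

  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  rot <- tr$accel
  rot$values <- R %*% rot$values
  # skewness sign rule makes the pipeline fully rotation invariant
  expect_lt(max(abs(build_input(rot)$x - x)), 1e-8)

  zero <- sampled_signal(matrix(0, 3, 100), tr$accel$fs)
  expect_error(build_input(zero), "degenerate")
})

test_that("segmentation at foot offs produces half-open FO-to-FO strides", {
  x <- matrix(rnorm(3 * 500), nrow = 3)
  z <- rnorm(500)
  ev <- gait_event_series(c(50, 200, 350), c(100, 250, 400), fs = 100)
  segs <- segment_at_foot_off(x, z, ev, preprocess_config(transient_samples = 36))
  expect_length(segs, 2)
  expect_equal(segs[[1]]$start, 100)
  expect_equal(segs[[1]]$end, 250)
  expect_equal(sum(segs[[1]]$mask), 150 - 72)
  expect_identical(segs[[2]]$z, z[250:399])

  segs0 <- segment_at_foot_off(x, z, ev, preprocess_config(transient_samples = 0))
  expect_true(all(segs0[[1]]$mask))
  # concatenating all segments reconstructs the span between first/last FO
  expect_identical(do.call(cbind, lapply(segs0, `[[`, "x")),
                   x[, 100:399])

  one_fo <- gait_event_series(50, 100, fs = 100)
  expect_warning(empty <- segment_at_foot_off(x, z, one_fo), "fewer than 2")
  expect_length(empty, 0)
})

test_that("one sample at the accelerometer rate is exactly 7 ms", {
  expect_identical(sample_period_ms(2000 / 14), 7)
})
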