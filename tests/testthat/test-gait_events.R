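test_that("scale_unit maps to [0, 1] exactly and is idempotent", {
  expect_equal(scale_unit(c(-1, 0, 3)), c(0, 0.25, 1))
  set.seed(1)
  v <- rnorm(300)
  s <- scale_unit(v)
  expect_identical(c(min(s), max(s)), c(0, 1))
  expect_equal(scale_unit(s), s, tolerance = 1e-15)
  expect_error(scale_unit(rep(2, 10)), "constant")
})

test_that("Savitzky-Golay window is 9 samples at the accelerometer rate", {
  expect_identical(sg_window_samples(30, 2000 / 14), 9L)
})

test_that("order-1 smoothing preserves lines and equals a moving mean", {
  fs <- 2000 / 14
  ramp <- seq(0, 5, length.out = 100)
  expect_lt(max(abs(smooth_savgol(ramp, fs = fs) - ramp)[5:96]), 1e-10)

  set.seed(2)
  v <- rnorm(200)
  sm <- smooth_savgol(v, fs = fs)
  ma <- stats::filter(v, rep(1 / 9, 9), sides = 2)
  expect_lt(max(abs(sm[5:196] - ma[5:196])), 1e-10)

  expect_error(smooth_savgol(rnorm(5), fs = fs), "longer than the signal")
})

test_that("detected events sit at the analytic threshold crossings", {
  fs <- 2000 / 14
  grf <- trapezoid_grf(n_pulses = 6, fs = fs)
  ev <- detect_events(grf)
  expect_length(ev$foot_contacts, 6)
  expect_length(ev$foot_offs, 6)

  # independent oracle: order-1 SG smoothing is a moving mean, so the
  # threshold crossings of the moving-averaged scaled pulse train can be
  # located directly with stats::filter
  v <- drop(grf$values)
  sc <- (v - min(v)) / (max(v) - min(v))
  sm <- stats::filter(sc, rep(1 / 9, 9), sides = 2)
  sm <- (sm - min(sm, na.rm = TRUE)) / diff(range(sm, na.rm = TRUE))
  above <- !is.na(sm) & sm >= 0.125
  up <- which(!above[-length(above)] & above[-1])        # FC = last below
  down <- which(above[-length(above)] & !above[-1]) + 1  # FO = first below
  expect_identical(ev$foot_contacts, as.integer(up))
  expect_identical(ev$foot_offs, as.integer(down))

  # the crossings sit within ~2 samples of the raw-ramp 12.5% point (the
  # 9-sample window is wider than the 50 ms ramp and widens it slightly)
  n_gap <- round(0.45 * fs)
  n_ramp <- max(2, round(0.05 * fs))
  n_plat <- round(0.4 * fs)
  period <- n_ramp * 2 + n_plat + n_gap
  for (k in 0:5) {
    onset <- n_gap + k * period + 1            # first nonzero sample
    expected_fc <- onset + 0.125 * (n_ramp - 1)
    expect_lt(abs(ev$foot_contacts[k + 1] - expected_fc), 2.5)
    offset <- onset + n_ramp + n_plat          # start of down ramp
    expected_fo <- offset + 0.875 * (n_ramp - 1)
    expect_lt(abs(ev$foot_offs[k + 1] - expected_fo), 2.5)
  }

  # crossing invariants on the smoothed scaled signal
  s <- scale_unit(smooth_savgol(scale_unit(v), fs = fs))
  for (fc in ev$foot_contacts) {
    expect_lt(s[fc], 0.125)
    expect_gte(s[fc + 1], 0.125)
  }
  for (fo in ev$foot_offs) {
    expect_lt(s[fo], 0.125)
    expect_gte(s[fo - 1], 0.125)
  }
})

test_that("detection is invariant to positive affine transforms", {
  grf <- trapezoid_grf(n_pulses = 4)
  ev <- detect_events(grf)
  shifted <- grf
  shifted$values <- 0.37 * shifted$values - 112
  ev2 <- detect_events(shifted)
  expect_identical(ev$foot_contacts, ev2$foot_contacts)
  expect_identical(ev$foot_offs, ev2$foot_offs)
})

test_that("degenerate inputs and jitter tie-breaks are handled", {
  # all-zero GRF: empty series + warning
  expect_warning(ev0 <- detect_events(rep(0, 200), fs = 100), "no threshold")
  expect_length(ev0$foot_contacts, 0)
  expect_length(ev0$foot_offs, 0)

  # single-sample spike is ignored; single-sample dip does not split stance
  fs <- 100
  base <- rep(0, 50)
  stance <- rep(1, 40)
  dip <- stance; dip[20] <- 0.01
  sig <- c(base, stance, base, dip, base)
  ev1 <- detect_events(sig, fs = fs,
                       config = event_detection_config(sg_halfwidth_ms = 1))
  expect_length(ev1$foot_contacts, 2)
  expect_length(ev1$foot_offs, 2)
  spike <- rep(0, 50); spike[25] <- 1
  ev2 <- detect_events(c(base, stance, base, spike, base), fs = fs,
                       config = event_detection_config(sg_halfwidth_ms = 1))
  expect_length(ev2$foot_contacts, 1)

  # min_phase debounce drops short stances
  short <- rep(1, 4)
  sig3 <- c(base, stance, base, short, base, stance, base)
  cfg3 <- event_detection_config(sg_halfwidth_ms = 1, min_phase_ms = 100)
  ev3 <- detect_events(sig3, fs = fs, config = cfg3)
  expect_length(ev3$foot_contacts, 2)
})

test_that("detection recovers generator ground truth on noise-free GRF", {
  w <- sg_window_samples(30, 2000 / 14)
  for (mode in c("walking", "running")) {
    spec <- synthetic_trial_spec(gait_pattern_spec(mode), n_strides = 25,
                                 seed = 13)
    tr <- synthesize_trial(spec, "t")
    rs <- resample_grf(tr$grf, tr$accel$fs)
    ev <- detect_events(rs)
    gt <- tr$events
    n <- ncol(rs$values)
    keep <- function(v) v[v > w & v < n - w]
    gtk <- gait_event_series(keep(gt$foot_contacts), keep(gt$foot_offs),
                             gt$fs)
    m <- match_events(ev, gtk)
    expect_equal(m$fc$unmatched_target, 0)
    expect_equal(m$fo$unmatched_target, 0)
    expect_lte(max(abs(m$fc$pairs$dt_samples)), 1)
    expect_lte(max(abs(m$fo$pairs$dt_samples)), 1)
  }
})
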