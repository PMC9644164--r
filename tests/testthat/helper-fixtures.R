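# Shared fixtures: all synthetic, built in code at test time.

# small paired walking/running cohort for pipeline tests
tiny_cohort <- function(n_per_mode = 2, n_strides = 20, seed = 7) {
  synthesize_cohort(n_per_mode = n_per_mode, n_strides = n_strides,
                    master_seed = seed)
}

# a valid random event series: alternating FC/FO with jittered gaps
random_events <- function(n_strides, fs = 2000 / 14, seed = 1) {
  set.seed(seed)
  gaps <- sample(40:80, 2 * n_strides, replace = TRUE)
  idx <- cumsum(gaps)
  gait_event_series(idx[seq(1, length(idx), by = 2)],
                    idx[seq(2, length(idx), by = 2)], fs = fs)
}

# trapezoid stance pulse train with linear ramps (analytic threshold times)
trapezoid_grf <- function(n_pulses = 5, fs = 2000 / 14, ramp_s = 0.05,
                          plateau_s = 0.4, gap_s = 0.45, amp = 1000) {
  dt <- 1 / fs
  one <- c(seq(0, amp, length.out = max(2, round(ramp_s * fs))),
           rep(amp, round(plateau_s * fs)),
           seq(amp, 0, length.out = max(2, round(ramp_s * fs))))
  gap <- rep(0, round(gap_s * fs))
  v <- c(gap, rep(c(one, gap), n_pulses))
  sampled_signal(v, fs = fs, labels = "Fz")
}

expect_relative_equal <- function(object, expected, tol = 1e-8) {
  expect_lt(max(abs(object - expected)) / max(abs(expected), 1e-300), tol)
}
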