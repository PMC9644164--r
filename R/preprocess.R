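# Raw-signal conditioning: turn tri-axial shank acceleration into the
# three-row network input x = (a_bar, v_bar, p_bar) and the vertical GRF
# into the z-scored target, and split data into FO-to-FO strides.

#' Preprocessing configuration
#'
#' @param hp_cutoff high-pass cutoff in Hz applied to the re-oriented
#'   acceleration before integration (default 1 Hz).
#' @param hp_order Butterworth order of a single pass (default 2; the
#'   filter is applied bidirectionally, so the effective attenuation is the
#'   squared single-pass magnitude).
#' @param target_fs working sampling rate in Hz; GRF recorded at a higher
#'   rate is decimated to this (default 2000/14 Hz, approx. 142.86 Hz).
#' @param transient_samples samples on either side of each foot off treated
#'   as transient and excluded from training/metrics on segmented data
#'   (default 36).
#' @param pca_sign_rule sign convention for the leading principal
#'   component. `"skewness-positive"` (default) flips the component so its
#'   sample skewness is positive: stance loading makes the force-aligned
#'   shank component right-skewed, so the rule is stable across sensor
#'   mountings and makes the whole input pipeline invariant under any
#'   rotation of the sensor axes. `"dominant-loading-positive"` instead
#'   makes the eigenvector's largest-magnitude loading positive (also used
#'   as the fallback when the skewness is numerically zero); it depends on
#'   the mounting orientation and can flip sign between trials whose two
#'   largest loadings are close.
#' @param hp_each_stage if `TRUE` (default), re-apply the high-pass to the
#'   velocity and position traces after each integration. Double
#'   integration of broadband sensor noise otherwise produces an aperiodic
#'   position wander that dominates the range-normalized position row and
#'   lets the readout memorize training strides instead of the gait
#'   phase; see the methods vignette. Set `FALSE` for the literal
#'   single-filter pipeline.
#' @export
preprocess_config <- function(hp_cutoff = 1, hp_order = 2,
                              target_fs = 2000 / 14, transient_samples = 36,
                              pca_sign_rule = c("skewness-positive",
                                                "dominant-loading-positive"),
                              hp_each_stage = TRUE) {
  stopifnot(hp_cutoff > 0, hp_order >= 1, transient_samples >= 0,
            target_fs > 0)
  pca_sign_rule <- match.arg(pca_sign_rule)
  structure(list(hp_cutoff = hp_cutoff, hp_order = hp_order,
                 target_fs = target_fs,
                 transient_samples = as.integer(transient_samples),
                 pca_sign_rule = pca_sign_rule,
                 hp_each_stage = isTRUE(hp_each_stage)),
            class = "preprocess_config")
}

#' Anti-aliased resampling of a GRF signal
#'
#' Rational-ratio resampling (`target_fs / fs` approximated by a small
#' rational number): zero-stuffing upsampling where needed, a Blackman
#' windowed-sinc anti-alias FIR applied with zero phase, then decimation.
#' For the default rates (1 kHz to 2000/14 Hz) this is plain decimation by
#' 7 and the output length is `ceiling(n / 7)`. Upsampling above the input
#' rate is out of scope and raises an error.
#'
#' @param grf a [sampled_signal()].
#' @param target_fs desired rate in Hz, `<= grf$fs`.
#' @return a [sampled_signal()] at `target_fs`.
#' @export
resample_grf <- function(grf, target_fs) {
  stopifnot(inherits(grf, "sampled_signal"))
  if (target_fs > grf$fs * (1 + 1e-12)) {
    stop("upsampling above the input rate is out of scope")
  }
  if (isTRUE(all.equal(target_fs, grf$fs))) return(grf)
  r <- rational_approx(target_fs / grf$fs)
  up <- r[["num"]]; down <- r[["den"]]
  vals <- t(apply(grf$values, 1, resample_vec, up = up, down = down))
  sampled_signal(vals, fs = grf$fs * up / down, labels = grf$labels,
                 t0 = grf$t0)
}

resample_vec <- function(x, up, down) {
  n <- length(x)
  if (up > 1) {
    xu <- numeric(n * up)
    xu[seq(1, n * up, by = up)] <- x * up
  } else {
    xu <- x
  }
  q <- max(up, down)
  ntaps <- 20L * q + 1L
  h <- fir_lowpass(ntaps, cutoff = 0.95 / q)
  y <- fir_filter_sym(h, xu)
  y[seq(1, length(xu), by = down)]
}

#' Re-orient tri-axial acceleration onto its principal axis
#'
#' Projects the mean-centered channels onto the unit leading eigenvector of
#' the 3x3 channel covariance (classic PCA "standardization" of sensor
#' orientation); only this first component is retained. The sign is fixed
#' by `sign_rule` (see [preprocess_config()]); the default skewness rule
#' makes the result deterministic and independent of how the sensor was
#' mounted.
#'
#' @param accel a 3-channel [sampled_signal()].
#' @param sign_rule `"skewness-positive"` or `"dominant-loading-positive"`.
#' @return a 1-channel [sampled_signal()] (label `a_hat`) whose variance is
#'   the leading eigenvalue.
#' @export
reorient_pca <- function(accel, sign_rule = c("skewness-positive",
                                              "dominant-loading-positive")) {
  sign_rule <- match.arg(sign_rule)
  stopifnot(inherits(accel, "sampled_signal"), n_channels(accel) == 3)
  if (n_samples(accel) < 3) stop("need at least 3 samples for PCA")
  X <- accel$values - rowMeans(accel$values)
  S <- tcrossprod(X) / (ncol(X) - 1)
  if (sum(diag(S)) <= .Machine$double.eps * 100) {
    stop("degenerate covariance")
  }
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v    # loading convention first
  a <- drop(crossprod(v, X))
  if (sign_rule == "skewness-positive") {
    sk <- mean(a^3) / (stats::sd(a)^3)
    if (is.finite(sk) && abs(sk) > 1e-8 && sk < 0) a <- -a
  }
  sampled_signal(a, fs = accel$fs, labels = "a_hat", t0 = accel$t0)
}

#' Bidirectional Butterworth high-pass
#'
#' Zero-phase (forward-backward) high-pass filtering of every channel.
#'
#' @param signal a [sampled_signal()].
#' @param cutoff cutoff in Hz (must be below Nyquist).
#' @param order single-pass Butterworth order.
#' @export
highpass_bidirectional <- function(signal, cutoff = 1, order = 2) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (cutoff >= signal$fs / 2) stop("cutoff must be below Nyquist")
  ba <- butter_design(order, cutoff, signal$fs, type = "high")
  vals <- t(apply(signal$values, 1, function(v) filtfilt(ba$b, ba$a, v)))
  sampled_signal(vals, fs = signal$fs, labels = signal$labels, t0 = signal$t0)
}

#' Cumulative trapezoidal integration over time
#'
#' @param signal a [sampled_signal()]; each channel is integrated with
#'   `dt = 1/fs` and initial value 0.
#' @export
integrate_cumulative <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  vals <- t(apply(signal$values, 1, cumtrapz_vec, fs = signal$fs))
  sampled_signal(vals, fs = signal$fs, labels = signal$labels, t0 = signal$t0)
}

cumtrapz_vec <- function(x, fs) {
  n <- length(x)
  if (n == 1) return(0)
  c(0, cumsum((x[-1] + x[-n]) / 2)) / fs
}

#' Range normalization
#'
#' Divides each channel by its range (max - min) so the output range is
#' exactly 1. There is no centering.
#'
#' @param signal a [sampled_signal()].
#' @export
range_normalize <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  vals <- t(apply(signal$values, 1, function(v) {
    r <- max(v) - min(v)
    if (r <= 0) stop("zero range")
    v / r
  }))
  sampled_signal(vals, fs = signal$fs, labels = signal$labels, t0 = signal$t0)
}

#' z-score a signal
#'
#' Per channel: subtract the mean, divide by the sample standard deviation
#' (denominator `n - 1`).
#'
#' @param signal a [sampled_signal()].
#' @export
zscore_signal <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  vals <- t(apply(signal$values, 1, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s <= 0) stop("constant signal cannot be z-scored")
    (v - mean(v)) / s
  }))
  sampled_signal(vals, fs = signal$fs, labels = signal$labels, t0 = signal$t0)
}

#' Build the three-row network input from tri-axial acceleration
#'
#' Pipeline: PCA re-orientation to `a_hat`, bidirectional high-pass, then
#' cumulative integration to velocity `v_hat` and again to position
#' `p_hat`; each of the three traces is range-normalized per trial and
#' stacked as the rows `a_bar`, `v_bar`, `p_bar` of the input matrix.
#'
#' @param accel 3-channel [sampled_signal()].
#' @param config a [preprocess_config()].
#' @return object of class `network_input`: list with `x` (3 x T matrix)
#'   and `fs`. Every row has range exactly 1.
#' @export
build_input <- function(accel, config = preprocess_config()) {
  a_hat <- reorient_pca(accel, sign_rule = config$pca_sign_rule)
  a_f <- highpass_bidirectional(a_hat, config$hp_cutoff, config$hp_order)
  v <- integrate_cumulative(a_f)
  if (config$hp_each_stage) {
    v <- highpass_bidirectional(v, config$hp_cutoff, config$hp_order)
  }
  p <- integrate_cumulative(v)
  if (config$hp_each_stage) {
    p <- highpass_bidirectional(p, config$hp_cutoff, config$hp_order)
  }
  x <- rbind(range_normalize(a_f)$values,
             range_normalize(v)$values,
             range_normalize(p)$values)
  rownames(x) <- c("a_bar", "v_bar", "p_bar")
  structure(list(x = x, fs = accel$fs), class = "network_input")
}

#' Segment input/target data into FO-to-FO strides
#'
#' One segment per consecutive pair of foot-off events, as the half-open
#' sample interval `[FO_i, FO_{i+1})`. Each segment carries a transient
#' mask: the first and last `transient_samples` samples are marked unusable
#' (FALSE) so that training and segment-wise metrics are independent of the
#' segment boundaries.
#'
#' @param x 3 x T input matrix (or `network_input`).
#' @param z length-T target vector.
#' @param events a [gait_event_series()] on the same sample grid.
#' @param config a [preprocess_config()] (supplies `transient_samples`).
#' @return list of `stride_segment` objects: `start`, `end` (half-open,
#'   1-based), `x`, `z`, `mask`.
#' @export
segment_at_foot_off <- function(x, z, events, config = preprocess_config()) {
  if (inherits(x, "network_input")) x <- x$x
  stopifnot(is.matrix(x), length(z) == ncol(x))
  fo <- events$foot_offs
  if (length(fo) < 2) {
    warning("fewer than 2 foot-off events: no segments")
    return(list())
  }
  tr <- config$transient_samples
  lapply(seq_len(length(fo) - 1), function(i) {
    start <- fo[i]
    end <- fo[i + 1]
    len <- end - start
    mask <- rep(TRUE, len)
    if (tr > 0) {
      k <- min(tr, len)
      mask[seq_len(k)] <- FALSE
      mask[seq(len - k + 1, len)] <- FALSE
    }
    structure(list(trial_id = attr(events, "trial_id"), start = start,
                   end = end, x = x[, seq(start, end - 1), drop = FALSE],
                   z = z[seq(start, end - 1)], mask = mask),
              class = "stride_segment")
  })
}

#' Milliseconds per sample at a given rate
#' @param fs sampling rate in Hz.
#' @return `1000 / fs`, e.g. exactly 7 ms at the default 2000/14 Hz.
#' @export
sample_period_ms <- function(fs = 2000 / 14) 1000 / fs
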