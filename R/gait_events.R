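# Threshold-based foot-contact / foot-off detection from a vertical GRF
# waveform (measured or predicted): unit scaling, weak Savitzky-Golay
# smoothing, then crossings of 12.5% of the maximum. The same code path is
# used for measured and predicted waveforms.

#' Event-detection configuration
#'
#' @param threshold_frac threshold as a fraction of the scaled maximum
#'   (default 0.125, i.e. 12.5% of the maximum).
#' @param sg_halfwidth_ms Savitzky-Golay half-window in ms (default 30 ms;
#'   at 2000/14 Hz this gives a 9-sample window).
#' @param sg_order Savitzky-Golay polynomial order (default 1; order-1
#'   smoothing equals a moving average in the interior).
#' @param min_phase_ms optional debounce: stance phases shorter than this
#'   are dropped. Default `NULL` (off).
#' @export
event_detection_config <- function(threshold_frac = 0.125,
                                   sg_halfwidth_ms = 30, sg_order = 1,
                                   min_phase_ms = NULL) {
  stopifnot(threshold_frac > 0, threshold_frac < 1, sg_order >= 1)
  structure(list(threshold_frac = threshold_frac,
                 sg_halfwidth_ms = sg_halfwidth_ms,
                 sg_order = as.integer(sg_order),
                 min_phase_ms = min_phase_ms),
            class = "event_detection_config")
}

#' Scale a signal to the unit interval
#'
#' `(s - min) / (max - min)`: minimum exactly 0, maximum exactly 1. The
#' detection pipeline is therefore invariant to positive affine transforms
#' of the input waveform.
#'
#' @param x numeric vector or 1-channel [sampled_signal()].
#' @export
scale_unit <- function(x) {
  if (inherits(x, "sampled_signal")) {
    out <- x
    out$values <- t(apply(x$values, 1, scale_unit))
    return(out)
  }
  r <- max(x) - min(x)
  if (r <= 0) stop("constant signal cannot be scaled to [0, 1]")
  (x - min(x)) / r
}

#' Savitzky-Golay window length for a half-width in milliseconds
#'
#' `2 * floor(halfwidth_ms / 1000 * fs) + 1` samples; 9 samples for
#' +/- 30 ms at 2000/14 Hz.
#'
#' @param halfwidth_ms half-window in ms.
#' @param fs sampling rate in Hz.
#' @export
sg_window_samples <- function(halfwidth_ms = 30, fs = 2000 / 14) {
  2L * as.integer(floor(halfwidth_ms / 1000 * fs)) + 1L
}

#' Weak Savitzky-Golay smoothing of a GRF waveform
#'
#' @param x numeric vector or 1-channel [sampled_signal()].
#' @param fs sampling rate (ignored when `x` is a signal).
#' @param config an [event_detection_config()].
#' @export
smooth_savgol <- function(x, fs = NULL, config = event_detection_config()) {
  if (inherits(x, "sampled_signal")) {
    out <- x
    out$values <- t(apply(x$values, 1, smooth_savgol, fs = x$fs,
                          config = config))
    return(out)
  }
  stopifnot(!is.null(fs))
  w <- sg_window_samples(config$sg_halfwidth_ms, fs)
  savgol_smooth(x, window = w, order = config$sg_order)
}

#' Detect foot-contact and foot-off events from a GRF waveform
#'
#' The waveform is scaled to \[0, 1\], weakly Savitzky-Golay smoothed (and
#' re-scaled so that the threshold is exactly `threshold_frac` of the
#' smoothed maximum), and compared against the threshold. For each stance
#' phase the foot contact is the last sample below the threshold before
#' the ascending crossing and the foot off the first sample below it after
#' the descending crossing. Supra-threshold runs shorter than 2 samples
#' (isolated spikes) are ignored; `min_phase_ms` additionally drops short
#' stance phases when set.
#'
#' @param grf numeric vector or 1-channel [sampled_signal()].
#' @param fs sampling rate in Hz (ignored when `grf` is a signal).
#' @param config an [event_detection_config()].
#' @param side side annotation for the returned series.
#' @return a [gait_event_series()]; empty (with a warning) if the waveform
#'   never crosses the threshold.
#' @export
detect_events <- function(grf, fs = NULL, config = event_detection_config(),
                          side = "right") {
  if (inherits(grf, "sampled_signal")) {
    fs <- grf$fs
    grf <- drop(grf$values[1, ])
  }
  stopifnot(!is.null(fs))
  if (max(grf) - min(grf) <= 0) {
    warning("no threshold crossings: empty event series")
    return(structure(list(foot_contacts = integer(0), foot_offs = integer(0),
                          fs = fs, side = side), class = "gait_event_series"))
  }
  s <- scale_unit(smooth_savgol(scale_unit(grf), fs = fs, config = config))
  th <- config$threshold_frac
  above <- s >= th
  # deterministic tie-breaks for jitter: isolated single-sample spikes and
  # dips do not open or close a stance phase
  repeat {
    r <- rle(above)
    short <- which(r$lengths < 2)
    short <- short[!(short %in% c(1, length(r$lengths)))]
    if (!length(short)) break
    ends <- cumsum(r$lengths)
    for (k in short) above[ends[k]] <- !r$values[k]
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= 2)
  if (!is.null(config$min_phase_ms)) {
    min_len <- config$min_phase_ms / 1000 * fs
    keep <- keep[r$lengths[keep] >= min_len]
  }
  fc <- integer(0)
  fo <- integer(0)
  for (k in keep) {
    if (starts[k] > 1) fc <- c(fc, starts[k] - 1L)
    if (ends[k] < length(s)) fo <- c(fo, ends[k] + 1L)
  }
  if (!length(fc) && !length(fo)) {
    warning("no threshold crossings: empty event series")
    return(structure(list(foot_contacts = integer(0), foot_offs = integer(0),
                          fs = fs, side = side), class = "gait_event_series"))
  }
  gait_event_series(fc, fo, fs = fs, side = side)
}
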