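# Domain containers (sampled signals, gait event series, trial records) and
# delimited-table readers/writers.
#
# Conventions used across the package:
#  * signals are channels-by-samples matrices with a sampling rate `fs`;
#  * sample indices are 1-based inside R (idiomatic R); the on-disk event
#    table format stores 0-based `sample_index` values and conversion
#    happens transparently in the readers/writers;
#  * time of sample k (1-based) is t0 + (k - 1) / fs.

#' Multichannel sampled signal
#'
#' @param values numeric matrix, channels x samples (a vector is treated as
#'   one channel). All values must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param labels optional character vector of channel names.
#' @param t0 start time in seconds (default 0).
#' @return object of class `sampled_signal` with fields `values`, `fs`,
#'   `labels`, `t0`.
#' @export
sampled_signal <- function(values, fs, labels = NULL, t0 = 0) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  stopifnot(is.matrix(values), is.numeric(values))
  if (ncol(values) < 1) stop("signal must contain at least one sample")
  if (!all(is.finite(values))) stop("signal values must be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a positive scalar")
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(values)))
  stopifnot(length(labels) == nrow(values))
  rownames(values) <- labels
  structure(list(values = values, fs = fs, labels = labels, t0 = t0),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d channel(s) x %d samples @ %.4f Hz (%.2f s)\n",
              nrow(x$values), ncol(x$values), x$fs,
              ncol(x$values) / x$fs))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(s) ncol(s$values)
n_channels <- function(s) nrow(s$values)

#' Sample times of a signal
#' @param s a [sampled_signal()].
#' @return numeric vector `t0 + (0:(n-1)) / fs`.
#' @export
signal_times <- function(s) s$t0 + (seq_len(n_samples(s)) - 1) / s$fs

# check strict FC/FO alternation; returns NULL if valid, else a message
alternation_violation <- function(fc, fo) {
  for (v in list(fc, fo)) {
    if (length(v) > 1 && any(diff(v) <= 0)) {
      return("event indices must be strictly increasing within each type")
    }
  }
  ev <- rbind(
    if (length(fc)) data.frame(type = "FC", idx = fc) else NULL,
    if (length(fo)) data.frame(type = "FO", idx = fo) else NULL
  )
  if (is.null(ev) || nrow(ev) < 2) return(NULL)
  ev <- ev[order(ev$idx), ]
  same <- which(ev$type[-1] == ev$type[-nrow(ev)])
  if (length(same)) {
    i <- same[1]
    return(sprintf("events do not alternate: %s@%d followed by %s@%d",
                   ev$type[i], ev$idx[i], ev$type[i + 1], ev$idx[i + 1]))
  }
  NULL
}

#' Gait event series (foot contacts and foot offs)
#'
#' Ordered 1-based sample indices of foot-contact (FC) and foot-off (FO)
#' events for a single trial and side. The merged sequence must strictly
#' alternate FC, FO, FC, ... (starting with either type).
#'
#' @param foot_contacts,foot_offs integer sample indices (1-based, sorted).
#' @param fs sampling rate of the signal the indices refer to, in Hz.
#' @param side `"left"` or `"right"`.
#' @export
gait_event_series <- function(foot_contacts, foot_offs, fs,
                              side = c("right", "left")) {
  side <- match.arg(side)
  fc <- as.integer(foot_contacts)
  fo <- as.integer(foot_offs)
  if (any(c(fc, fo) < 1)) stop("event sample indices must be >= 1")
  msg <- alternation_violation(fc, fo)
  if (!is.null(msg)) stop(msg)
  structure(list(foot_contacts = fc, foot_offs = fo, fs = fs, side = side),
            class = "gait_event_series")
}

#' @export
print.gait_event_series <- function(x, ...) {
  cat(sprintf("<gait_event_series> %d FC, %d FO @ %.4f Hz (%s side)\n",
              length(x$foot_contacts), length(x$foot_offs), x$fs, x$side))
  invisible(x)
}

#' One walking or running trial
#'
#' @param trial_id character identifier.
#' @param mode `"walking"` or `"running"`.
#' @param speed belt/locomotion speed in m/s.
#' @param accel 3-channel [sampled_signal()] of shank acceleration.
#' @param grf 1-channel [sampled_signal()] of vertical GRF.
#' @param events optional [gait_event_series()].
#' @export
trial_record <- function(trial_id, mode = c("walking", "running"), speed,
                         accel, grf, events = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(accel, "sampled_signal"), inherits(grf, "sampled_signal"))
  if (n_channels(accel) != 3) stop("accel must have exactly 3 channels")
  if (n_channels(grf) != 1) stop("grf must have exactly 1 channel")
  if (!is.null(events)) {
    stopifnot(inherits(events, "gait_event_series"))
    if (isTRUE(all.equal(events$fs, grf$fs))) {
      if (any(c(events$foot_contacts, events$foot_offs) > n_samples(grf))) {
        stop("event indices exceed grf length")
      }
    }
  }
  structure(list(trial_id = trial_id, mode = mode, speed = speed,
                 accel = accel, grf = grf, events = events),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s: %s @ %.2f m/s; accel %d samples @ %.2f Hz, grf %d samples @ %.2f Hz\n",
              x$trial_id, x$mode, x$speed, n_samples(x$accel), x$accel$fs,
              n_samples(x$grf), x$grf$fs))
  invisible(x)
}

# sniff the field separator of a delimited text file from its header line
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a signal table
#'
#' Reads a delimited table (comma- or tab-separated, sniffed from the
#' header) whose first column is time in seconds and remaining columns are
#' numeric channels. The sampling rate is inferred from the median time
#' step; step jitter above 1% triggers a warning.
#'
#' @param path file path.
#' @param fs_override optional sampling rate in Hz, bypassing inference.
#' @return a [sampled_signal()].
#' @export
read_signal_table <- function(path, fs_override = NULL) {
  stopifnot(file.exists(path))
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("signal table needs a time column plus >= 1 channel")
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop(sprintf("non-numeric cell in column '%s', row %d",
                   names(df)[j], bad))
    }
  }
  tt <- df[[1]]
  if (length(tt) > 1) {
    dt <- diff(tt)
    if (any(dt <= 0)) stop("non-monotonic time")
    med <- stats::median(dt)
    if (max(abs(dt - med)) / med > 0.01) {
      warning(sprintf("time-step jitter exceeds 1%% (median step %.6g s)", med))
    }
    fs <- if (is.null(fs_override)) 1 / med else fs_override
  } else {
    if (is.null(fs_override)) stop("cannot infer fs from a single sample")
    fs <- fs_override
  }
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  sampled_signal(vals, fs = fs, labels = names(df)[-1], t0 = tt[1])
}

#' Write a signal table
#'
#' Inverse of [read_signal_table()]: comma-separated text with a
#' reconstructed `time_s` column. Round-tripping reproduces values to
#' better than 1e-9 relative.
#'
#' @param signal a [sampled_signal()].
#' @param path output file path.
#' @export
write_signal_table <- function(signal, path) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (nrow(signal$values) == 0) stop("no channels")
  df <- data.frame(time_s = signal_times(signal), check.names = FALSE)
  for (i in seq_len(n_channels(signal))) {
    df[[signal$labels[i]]] <- signal$values[i, ]
  }
  cols <- vapply(df, function(v) format(v, digits = 17, trim = TRUE,
                                        scientific = FALSE), character(nrow(df)))
  lines <- c(paste(names(df), collapse = ","),
             apply(matrix(cols, nrow = nrow(df)), 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write gait event tables
#'
#' Event tables are CSV with columns `event_type` (`FC`/`FO`),
#' `sample_index` (0-based on disk, converted to 1-based in R) and
#' `time_s`. The FC/FO alternation invariant is checked on load.
#'
#' @param path file path.
#' @param fs sampling rate to attach; if `NULL`, recovered from
#'   `sample_index` vs `time_s`.
#' @param side event side annotation.
#' @return a [gait_event_series()].
#' @export
read_event_table <- function(path, fs = NULL, side = "right") {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("event_type", "sample_index", "time_s") %in% names(df)))
  if (!all(df$event_type %in% c("FC", "FO"))) {
    stop("event_type must be 'FC' or 'FO'")
  }
  if (any(df$sample_index < 0)) stop("sample_index must be >= 0")
  if (is.null(fs)) {
    nz <- df$sample_index > 0
    fs <- if (any(nz)) stats::median(df$sample_index[nz] / df$time_s[nz]) else 1
  }
  idx <- as.integer(df$sample_index) + 1L
  gait_event_series(idx[df$event_type == "FC"], idx[df$event_type == "FO"],
                    fs = fs, side = side)
}

#' @rdname read_event_table
#' @param events a [gait_event_series()].
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "gait_event_series"))
  df <- rbind(
    data.frame(event_type = rep("FC", length(events$foot_contacts)),
               sample_index = events$foot_contacts - 1L),
    data.frame(event_type = rep("FO", length(events$foot_offs)),
               sample_index = events$foot_offs - 1L)
  )
  df <- df[order(df$sample_index), ]
  df$time_s <- df$sample_index / events$fs
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a trial manifest
#'
#' A manifest is a CSV with columns `trial_id`, `mode`, `speed_mps`,
#' `accel_path`, `grf_path`, `events_path` (paths relative to the manifest
#' location). [write_trial_cohort()] writes every trial's signal and event
#' tables next to the manifest.
#'
#' @param trials list of [trial_record()] objects.
#' @param dir output directory (created if needed).
#' @return path of the written manifest.
#' @export
write_trial_cohort <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(trials, function(tr) {
    ap <- paste0(tr$trial_id, "_accel.csv")
    gp <- paste0(tr$trial_id, "_grf.csv")
    ep <- if (!is.null(tr$events)) paste0(tr$trial_id, "_events.csv") else ""
    write_signal_table(tr$accel, file.path(dir, ap))
    write_signal_table(tr$grf, file.path(dir, gp))
    if (nzchar(ep)) write_event_table(tr$events, file.path(dir, ep))
    data.frame(trial_id = tr$trial_id, mode = tr$mode, speed_mps = tr$speed,
               accel_path = ap, grf_path = gp, events_path = ep)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' @rdname write_trial_cohort
#' @param manifest_path path to a `manifest.csv`.
#' @export
read_trial_cohort <- function(manifest_path) {
  dir <- dirname(manifest_path)
  df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    accel <- read_signal_table(file.path(dir, df$accel_path[i]))
    grf <- read_signal_table(file.path(dir, df$grf_path[i]))
    ev <- NULL
    if (!is.na(df$events_path[i]) && nzchar(df$events_path[i])) {
      ev <- read_event_table(file.path(dir, df$events_path[i]))
    }
    trial_record(df$trial_id[i], df$mode[i], df$speed_mps[i],
                 accel, grf, ev)
  })
}
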