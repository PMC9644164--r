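# Prediction-quality metrics (range-normalized RMSE and R^2), event
# matching, and event-timing mean absolute errors.

#' Range-normalized root-mean-square error
#'
#' `sqrt(mean((z - y)^2)) / (max(z) - min(z))`, reported as a fraction
#' (multiply by 100 for percent). Invariant to joint rescaling of `y` and
#' `z`.
#'
#' @param y predicted values.
#' @param z target values (non-constant).
#' @export
nrmse <- function(y, z) {
  stopifnot(length(y) == length(z))
  rg <- max(z) - min(z)
  if (rg <= 0) stop("target range is zero")
  sqrt(mean((z - y)^2)) / rg
}

#' Coefficient of determination
#'
#' `1 - SSE / SST` with the total sum of squares about the mean of the
#' target; at most 1, unbounded below.
#'
#' @param y predicted values.
#' @param z target values (non-constant).
#' @export
r_squared <- function(y, z) {
  stopifnot(length(y) == length(z))
  sst <- sum((z - mean(z))^2)
  if (sst <= 0) stop("target variance is zero")
  1 - sum((z - y)^2) / sst
}

#' Match predicted to target gait events
#'
#' Per event type, greedy nearest-neighbour matching on absolute time
#' difference: pairs are accepted in order of increasing |dt| (ties broken
#' toward the earlier target event), each event used at most once, and
#' pairs further apart than `max_lag_ms` are rejected. The default lag
#' bound is 50% of the median target stride (FO-to-FO) duration.
#'
#' @param pred,target [gait_event_series()] objects at the same rate.
#' @param max_lag_ms maximum |dt| for a match, in ms.
#' @return list with per-type data frames of matched pairs (`target_idx`,
#'   `pred_idx`, `dt_samples`) and unmatched counts.
#' @export
match_events <- function(pred, target, max_lag_ms = NULL) {
  stopifnot(isTRUE(all.equal(pred$fs, target$fs)))
  fs <- target$fs
  if (is.null(max_lag_ms)) {
    fo <- target$foot_offs
    max_lag_ms <- if (length(fo) >= 2) {
      0.5 * stats::median(diff(fo)) * 1000 / fs
    } else {
      Inf
    }
  }
  if (!length(target$foot_contacts) && !length(target$foot_offs)) {
    warning("empty target event series: nothing to match")
  }
  match_one <- function(p, t) {
    if (!length(p) || !length(t)) {
      return(list(pairs = data.frame(target_idx = integer(0),
                                     pred_idx = integer(0),
                                     dt_samples = numeric(0)),
                  unmatched_target = length(t), unmatched_pred = length(p)))
    }
    cand <- expand.grid(ti = seq_along(t), pi = seq_along(p))
    cand$dt <- abs(t[cand$ti] - p[cand$pi])
    cand <- cand[cand$dt * 1000 / fs <= max_lag_ms, , drop = FALSE]
    cand <- cand[order(cand$dt, t[cand$ti]), , drop = FALSE]
    used_t <- logical(length(t)); used_p <- logical(length(p))
    rows <- list()
    for (i in seq_len(nrow(cand))) {
      ti <- cand$ti[i]; pi <- cand$pi[i]
      if (used_t[ti] || used_p[pi]) next
      used_t[ti] <- TRUE; used_p[pi] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(target_idx = t[ti],
                                             pred_idx = p[pi],
                                             dt_samples = p[pi] - t[ti])
    }
    pairs <- if (length(rows)) do.call(rbind, rows) else
      data.frame(target_idx = integer(0), pred_idx = integer(0),
                 dt_samples = numeric(0))
    pairs <- pairs[order(pairs$target_idx), , drop = FALSE]
    list(pairs = pairs, unmatched_target = sum(!used_t),
         unmatched_pred = sum(!used_p))
  }
  fc <- match_one(pred$foot_contacts, target$foot_contacts)
  fo <- match_one(pred$foot_offs, target$foot_offs)
  list(fc = fc, fo = fo, fs = fs, max_lag_ms = max_lag_ms)
}

#' Event-timing mean absolute error in milliseconds
#'
#' @param matches a [match_events()] result.
#' @return list `mae_fc_ms`, `mae_fo_ms` (`NA` when a type has no matched
#'   pairs, flagged by `defined_fc` / `defined_fo`).
#' @export
event_mae_ms <- function(matches) {
  fs <- matches$fs
  mae <- function(m) {
    if (!nrow(m$pairs)) return(NA_real_)
    mean(abs(m$pairs$dt_samples)) * 1000 / fs
  }
  list(mae_fc_ms = mae(matches$fc), mae_fo_ms = mae(matches$fo),
       defined_fc = nrow(matches$fc$pairs) > 0,
       defined_fo = nrow(matches$fo$pairs) > 0)
}

#' Evaluate a predicted GRF trace against its target
#'
#' Computes the waveform metrics (optionally on transient-masked samples)
#' and runs the same event detector on the predicted and target waveforms,
#' matches the events, and reports timing MAEs and match counts.
#'
#' @param y predicted z-scored GRF (numeric vector).
#' @param z target z-scored GRF (same length).
#' @param fs sampling rate in Hz.
#' @param event_config an [event_detection_config()].
#' @param mask optional logical vector; metrics use only `TRUE` samples
#'   (event detection always sees the full traces).
#' @return object of class `evaluation_report`: `epsilon`, `r2`,
#'   `mae_fc_ms`, `mae_fo_ms`, matched/unmatched counts.
#' @export
evaluate_trial <- function(y, z, fs, event_config = event_detection_config(),
                           mask = NULL) {
  stopifnot(length(y) == length(z))
  ym <- y; zm <- z
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(z))
    ym <- y[mask]; zm <- z[mask]
  }
  eps <- nrmse(ym, zm)
  r2 <- r_squared(ym, zm)
  ev_t <- suppressWarnings(detect_events(z, fs = fs, config = event_config))
  ev_p <- suppressWarnings(detect_events(y, fs = fs, config = event_config))
  m <- suppressWarnings(match_events(ev_p, ev_t))
  mm <- event_mae_ms(m)
  structure(list(epsilon = eps, r2 = r2,
                 mae_fc_ms = mm$mae_fc_ms, mae_fo_ms = mm$mae_fo_ms,
                 n_matched_fc = nrow(m$fc$pairs),
                 n_matched_fo = nrow(m$fo$pairs),
                 n_unmatched_target = m$fc$unmatched_target +
                   m$fo$unmatched_target,
                 n_unmatched_pred = m$fc$unmatched_pred +
                   m$fo$unmatched_pred),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> epsilon = %.3f%%, R2 = %.4f, MAE FC = %.1f ms, MAE FO = %.1f ms (%d/%d matched, %d+%d unmatched)\n",
              100 * x$epsilon, x$r2, x$mae_fc_ms, x$mae_fo_ms,
              x$n_matched_fc, x$n_matched_fo,
              x$n_unmatched_target, x$n_unmatched_pred))
  invisible(x)
}

#' Flatten an evaluation report to a one-row data frame
#' @param report an `evaluation_report`.
#' @export
report_as_row <- function(report) {
  data.frame(epsilon = report$epsilon, r2 = report$r2,
             mae_fc_ms = report$mae_fc_ms, mae_fo_ms = report$mae_fo_ms,
             n_matched_fc = report$n_matched_fc,
             n_matched_fo = report$n_matched_fo,
             n_unmatched_target = report$n_unmatched_target,
             n_unmatched_pred = report$n_unmatched_pred)
}
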