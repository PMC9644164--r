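# Training/validation schemes: segmented-train / continuous-test with a
# continuation rule, the repetition harness, training-size sweeps, and
# leave-M-out cross-validation by trial.

#' Protocol configuration
#'
#' @param n_repetitions independent repetitions of the split/train/test
#'   cycle (default 100).
#' @param max_validation_attempts re-initializations allowed by the
#'   continuation rule before training is declared stopped (default 100).
#' @param strides_cap_per_trial maximum training strides kept per trial
#'   (default 25, for a balanced design).
#' @param train_fraction fraction of each trial's strides used for
#'   training (default 0.5); the continuous holdout window is always 50%
#'   of the trial, split into a 25% validation and a 25% test half.
#' @param sweep_fractions training fractions for the size sweep (default
#'   4%..50%).
#' @param lmo_m number of trials held out per leave-M-out fold.
#' @param lmo_repetitions folds drawn when `lmo_m > 1` (default 42).
#' @param seed master seed for the whole protocol.
#' @export
protocol_config <- function(n_repetitions = 100,
                            max_validation_attempts = 100,
                            strides_cap_per_trial = 25,
                            train_fraction = 0.5,
                            sweep_fractions = c(0.04, 0.1, 0.2, 0.3, 0.4, 0.5),
                            lmo_m = 1, lmo_repetitions = 42, seed = 1L) {
  stopifnot(n_repetitions >= 1, max_validation_attempts >= 0,
            strides_cap_per_trial >= 1,
            train_fraction > 0, train_fraction <= 0.5,
            all(sweep_fractions > 0), all(sweep_fractions <= 0.5),
            lmo_m >= 1, lmo_repetitions >= 1)
  structure(list(n_repetitions = as.integer(n_repetitions),
                 max_validation_attempts = as.integer(max_validation_attempts),
                 strides_cap_per_trial = as.integer(strides_cap_per_trial),
                 train_fraction = train_fraction,
                 sweep_fractions = sweep_fractions,
                 lmo_m = as.integer(lmo_m),
                 lmo_repetitions = as.integer(lmo_repetitions),
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Prepare a trial for learning
#'
#' Resamples the GRF to the accelerometer rate, z-scores it per trial,
#' builds the three-row network input from the acceleration, and aligns
#' the lengths.
#'
#' @param trial a [trial_record()] with events.
#' @param config a [preprocess_config()].
#' @return list with `trial_id`, `mode`, `x` (3 x T), `z` (length T),
#'   `fs`, `events`, `n`.
#' @export
prepare_trial <- function(trial, config = preprocess_config()) {
  stopifnot(inherits(trial, "trial_record"))
  if (is.null(trial$events)) stop("trial has no events")
  grf <- resample_grf(trial$grf, trial$accel$fs)
  z <- drop(zscore_signal(grf)$values[1, ])
  xin <- build_input(trial$accel, config)
  n <- min(ncol(xin$x), length(z))
  ev <- trial$events
  keep_fc <- ev$foot_contacts[ev$foot_contacts <= n]
  keep_fo <- ev$foot_offs[ev$foot_offs <= n]
  list(trial_id = trial$trial_id, mode = trial$mode,
       x = xin$x[, seq_len(n), drop = FALSE], z = z[seq_len(n)],
       fs = trial$accel$fs,
       events = gait_event_series(keep_fc, keep_fo, fs = trial$accel$fs),
       n = n)
}

prepare_trials <- function(trials, config = preprocess_config()) {
  if (length(trials) && inherits(trials[[1]], "trial_record")) {
    lapply(trials, prepare_trial, config = config)
  } else {
    trials
  }
}

#' Draw a segmented-training / continuous-holdout split
#'
#' Per trial: one contiguous, stride-aligned window covering 50% of the
#' strides is held out; its first half (in time) is the validation trace
#' and its second half the test trace. The remaining strides (FO-to-FO)
#' are training candidates, of which a seeded random subsample of
#' `round(n_strides * train_fraction)` (at most `strides_cap_per_trial`)
#' is kept. Training strides and the holdout window are disjoint by
#' construction.
#'
#' @param ptrials list of prepared trials (see [prepare_trial()]).
#' @param config a [protocol_config()].
#' @param seed split seed.
#' @return object of class `split_plan`: per-trial list with `val`
#'   `[start, end)`, `test` `[start, end)` and `train_strides` (matrix of
#'   stride `[start, end)` rows).
#' @export
make_segmented_split <- function(ptrials, config = protocol_config(),
                                 seed = config$seed) {
  plan <- with_seed(seed, lapply(ptrials, function(pt) {
    fo <- pt$events$foot_offs
    n_str <- length(fo) - 1
    if (n_str < 4) {
      stop(sprintf("trial %s: too few strides (%d) for a 50/25/25 split",
                   pt$trial_id, n_str))
    }
    m_hold <- max(2L, round(n_str * 0.5))
    if (m_hold >= n_str) {
      stop(sprintf("trial %s: too few strides to hold out 50%%", pt$trial_id))
    }
    s <- sample.int(n_str - m_hold + 1L, 1L)
    w_start <- fo[s]
    w_end <- fo[s + m_hold]
    mid <- w_start + (w_end - w_start) %/% 2L
    cand <- setdiff(seq_len(n_str), seq(s, s + m_hold - 1L))
    n_train <- min(config$strides_cap_per_trial,
                   max(1L, round(n_str * config$train_fraction)),
                   length(cand))
    chosen <- sort(sample(cand, n_train))
    list(trial_id = pt$trial_id,
         val = c(w_start, mid), test = c(mid, w_end),
         train_strides = cbind(start = fo[chosen], end = fo[chosen + 1L]),
         n_strides = n_str)
  }))
  structure(plan, class = "split_plan", seed = seed)
}

# Cut training segments (x, z, transient mask) out of prepared trials.
# The transient here is a state washout: each segment starts at a foot off
# with q0 = 0, so its first `transient_samples` samples are excluded from
# the readout fit while the reservoir entrains. The trailing samples are
# kept: an FO-to-FO running stride is barely longer than two transients,
# and masking its tail would remove the entire stance phase from the
# training target (see the methods vignette).
assemble_training <- function(ptrials, plan, preprocess = preprocess_config()) {
  xs <- list(); zs <- list(); ms <- list()
  tr <- preprocess$transient_samples
  for (i in seq_along(ptrials)) {
    pt <- ptrials[[i]]
    st <- plan[[i]]$train_strides
    for (k in seq_len(nrow(st))) {
      a <- st[k, 1]; b <- st[k, 2]
      len <- b - a
      mask <- rep(TRUE, len)
      if (tr > 0) mask[seq_len(min(tr, len))] <- FALSE
      xs[[length(xs) + 1]] <- pt$x[, seq(a, b - 1), drop = FALSE]
      zs[[length(zs) + 1]] <- pt$z[seq(a, b - 1)]
      ms[[length(ms) + 1]] <- mask
    }
  }
  list(x = xs, z = zs, mask = ms)
}

slice_trace <- function(pt, win) {
  list(x = pt$x[, seq(win[1], win[2] - 1), drop = FALSE],
       z = pt$z[seq(win[1], win[2] - 1)])
}

#' Train a readout under the continuation rule
#'
#' Repeatedly draws a fresh reservoir (new sub-seed), fits the readout on
#' the training segments and checks the per-trial validation R^2. If all
#' validation R^2 are positive the network is accepted; otherwise a new
#' attempt is made, up to `max_attempts`. Failure is a reported state
#' (`passed = FALSE`), not an error.
#'
#' @param training list with `x`, `z`, `mask` (from the split assembly).
#' @param val_traces list of `list(x, z)` continuous validation traces.
#' @param esn an [esn_config()].
#' @param max_attempts maximum attempts.
#' @param base_seed seed from which per-attempt network seeds are derived.
#' @return list: `esn` (trained), `attempts`, `passed`, `val_r2`,
#'   `reason`.
#' @export
fit_with_continuation <- function(training, val_traces,
                                  esn = esn_config(), max_attempts = 100,
                                  base_seed = esn$seed) {
  stopifnot(length(training$x) >= 1, length(val_traces) >= 1)
  last <- NULL
  if (max_attempts < 1) {
    return(list(esn = NULL, attempts = 0L, passed = FALSE,
                val_r2 = numeric(0), reason = "no attempts allowed"))
  }
  for (attempt in seq_len(max_attempts)) {
    cfg <- esn
    cfg$seed <- derive_seed(base_seed, attempt)
    net <- init_network(cfg, n_inputs = nrow(training$x[[1]]))
    states <- with_seed(derive_seed(base_seed, 50000L + attempt), {
      lapply(training$x, function(xx) run_states(net, xx, noise_on = TRUE))
    })
    fit <- fit_readout(states, training$z, training$mask,
                       lambda = cfg$ridge_lambda)
    net <- set_readout(net, fit$W)
    val_r2 <- vapply(val_traces, function(v) {
      tryCatch(r_squared(predict_grf(net, v$x), v$z),
               error = function(e) NA_real_)
    }, numeric(1))
    passed <- all(is.finite(val_r2)) && all(val_r2 > 0)
    last <- list(esn = net, attempts = attempt, passed = passed,
                 val_r2 = val_r2, residual_rms = fit$residual_rms,
                 reason = if (passed) "validation passed" else
                   if (any(!is.finite(val_r2))) "validation R2 undefined"
                 else "validation R2 not all positive")
    if (passed) break
  }
  last
}

#' Run repeated segmented-train / continuous-test evaluations
#'
#' The main protocol: `n_repetitions` independent seeded draws of the
#' 50/25/25 split, training with the continuation rule, and evaluation on
#' each trial's continuous test quarter.
#'
#' @param trials list of [trial_record()] or prepared trials.
#' @param config a [protocol_config()].
#' @param esn an [esn_config()].
#' @param preprocess a [preprocess_config()].
#' @param events an [event_detection_config()].
#' @return data.frame with one row per repetition x trial (metrics, stride
#'   counts, attempt counts); summary via [summarize_repetitions()].
#' @export
run_repetitions <- function(trials, config = protocol_config(),
                            esn = esn_config(),
                            preprocess = preprocess_config(),
                            events = event_detection_config()) {
  ptrials <- prepare_trials(trials, preprocess)
  rows <- list()
  for (rep in seq_len(config$n_repetitions)) {
    seed_rep <- derive_seed(config$seed, rep)
    res <- tryCatch({
      plan <- make_segmented_split(ptrials, config, seed = seed_rep)
      training <- assemble_training(ptrials, plan, preprocess)
      val_traces <- lapply(seq_along(ptrials), function(i) {
        slice_trace(ptrials[[i]], plan[[i]]$val)
      })
      fit <- fit_with_continuation(training, val_traces, esn,
                                   config$max_validation_attempts,
                                   base_seed = derive_seed(seed_rep, 7L))
      n_train <- sum(vapply(plan, function(p) nrow(p$train_strides),
                            integer(1)))
      if (!fit$passed) {
        data.frame(repetition = rep, trial_id = NA_character_,
                   mode = NA_character_, epsilon = NA_real_, r2 = NA_real_,
                   mae_fc_ms = NA_real_, mae_fo_ms = NA_real_,
                   n_matched_fc = NA_integer_, n_matched_fo = NA_integer_,
                   n_unmatched_target = NA_integer_,
                   n_unmatched_pred = NA_integer_,
                   n_train_strides = n_train,
                   attempts = fit$attempts, passed = FALSE)
      } else {
        do.call(rbind, lapply(seq_along(ptrials), function(i) {
          te <- slice_trace(ptrials[[i]], plan[[i]]$test)
          y <- predict_grf(fit$esn, te$x)
          # washout: predictions start from q0 = 0, so the first
          # transient_samples of the continuous trace are discarded
          keep <- seq(min(preprocess$transient_samples + 1, length(y)),
                      length(y))
          rep_i <- evaluate_trial(y[keep], te$z[keep], ptrials[[i]]$fs,
                                  events)
          cbind(data.frame(repetition = rep,
                           trial_id = ptrials[[i]]$trial_id,
                           mode = ptrials[[i]]$mode),
                report_as_row(rep_i),
                data.frame(n_train_strides = n_train,
                           attempts = fit$attempts, passed = TRUE))
        }))
      }
    }, error = function(e) {
      data.frame(repetition = rep, trial_id = NA_character_,
                 mode = NA_character_, epsilon = NA_real_, r2 = NA_real_,
                 mae_fc_ms = NA_real_, mae_fo_ms = NA_real_,
                 n_matched_fc = NA_integer_, n_matched_fo = NA_integer_,
                 n_unmatched_target = NA_integer_,
                 n_unmatched_pred = NA_integer_,
                 n_train_strides = NA_integer_, attempts = NA_integer_,
                 passed = FALSE)
    })
    rows[[rep]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a repetition table
#'
#' Per-repetition means over trials, then mean and SD across repetitions
#' (the usual grand-average convention).
#'
#' @param df a [run_repetitions()] result.
#' @return data.frame with columns `metric`, `mean`, `sd`, `n_repetitions`.
#' @export
summarize_repetitions <- function(df) {
  ok <- df[df$passed %in% TRUE & !is.na(df$r2), , drop = FALSE]
  metrics <- c("epsilon", "r2", "mae_fc_ms", "mae_fo_ms", "n_train_strides")
  per_rep <- stats::aggregate(ok[metrics], by = list(repetition = ok$repetition),
                              FUN = mean, na.rm = TRUE)
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(metric = m, mean = mean(per_rep[[m]]),
               sd = stats::sd(per_rep[[m]]),
               n_repetitions = nrow(per_rep))
  }))
}

#' Sweep the training-set size
#'
#' Re-runs the repetition harness for each training fraction; the
#' validation and test windows stay fixed at 25% each.
#'
#' @param trials list of trials (raw or prepared).
#' @param fractions ascending training fractions (each <= 0.5).
#' @param config,esn,preprocess,events as in [run_repetitions()].
#' @return data.frame with one row per fraction: mean/SD of the stride
#'   count and of each metric across repetitions.
#' @export
sweep_training_fraction <- function(trials,
                                    fractions = protocol_config()$sweep_fractions,
                                    config = protocol_config(),
                                    esn = esn_config(),
                                    preprocess = preprocess_config(),
                                    events = event_detection_config()) {
  stopifnot(!is.unsorted(fractions), all(fractions <= 0.5))
  ptrials <- prepare_trials(trials, preprocess)
  do.call(rbind, lapply(fractions, function(f) {
    cfg <- config
    cfg$train_fraction <- f
    df <- run_repetitions(ptrials, cfg, esn, preprocess, events)
    s <- summarize_repetitions(df)
    row <- data.frame(fraction = f)
    for (m in s$metric) {
      row[[paste0(m, "_mean")]] <- s$mean[s$metric == m]
      row[[paste0(m, "_sd")]] <- s$sd[s$metric == m]
    }
    row
  }))
}

#' Leave-M-out fold plan
#'
#' For `M = 1`, one fold per trial (every trial held out exactly once).
#' For `M > 1`, `repetitions` seeded random draws of distinct held-out
#' sets.
#'
#' @param trial_ids character vector of trial identifiers.
#' @param m trials held out per fold (`m < length(trial_ids)`).
#' @param repetitions folds drawn when `m > 1`.
#' @param seed draw seed.
#' @return list of character vectors of held-out trial ids.
#' @export
lmo_fold_plan <- function(trial_ids, m = 1, repetitions = 42, seed = 1L) {
  n <- length(trial_ids)
  if (m >= n) stop("M must be smaller than the number of trials")
  if (m == 1) return(as.list(trial_ids))
  with_seed(seed, {
    seen <- character(0)
    folds <- list()
    guard <- 0L
    while (length(folds) < repetitions && guard < repetitions * 1000L) {
      guard <- guard + 1L
      f <- sort(sample(trial_ids, m))
      key <- paste(f, collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      folds[[length(folds) + 1]] <- f
    }
    folds
  })
}

#' Leave-M-out cross-validation by trial
#'
#' Per fold, the held-in trials are split 75/25 into training strides
#' (capped at `strides_cap_per_trial` per trial) and a contiguous,
#' stride-aligned continuous validation window; training uses the
#' continuation rule; testing runs on the full continuous held-out
#' trials.
#'
#' @param trials list of trials (raw or prepared).
#' @param m trials held out per fold.
#' @param config,esn,preprocess,events as in [run_repetitions()].
#' @return data.frame with one row per fold x held-out trial.
#' @export
leave_m_out <- function(trials, m = 1, config = protocol_config(),
                        esn = esn_config(),
                        preprocess = preprocess_config(),
                        events = event_detection_config()) {
  ptrials <- prepare_trials(trials, preprocess)
  ids <- vapply(ptrials, function(p) p$trial_id, character(1))
  if (m >= length(ids)) stop("M must be smaller than the number of trials")
  folds <- lmo_fold_plan(ids, m, config$lmo_repetitions, config$seed)
  rows <- list()
  for (k in seq_along(folds)) {
    held_out <- folds[[k]]
    seed_fold <- derive_seed(config$seed, 300000L + k)
    in_idx <- which(!(ids %in% held_out))
    out_idx <- which(ids %in% held_out)
    plan <- with_seed(seed_fold, lapply(ptrials[in_idx], function(pt) {
      fo <- pt$events$foot_offs
      n_str <- length(fo) - 1
      if (n_str < 4) stop(sprintf("trial %s: too few strides", pt$trial_id))
      m_val <- max(1L, round(n_str * 0.25))
      s <- sample.int(n_str - m_val + 1L, 1L)
      cand <- setdiff(seq_len(n_str), seq(s, s + m_val - 1L))
      n_train <- min(config$strides_cap_per_trial, length(cand))
      chosen <- sort(sample(cand, n_train))
      list(val = c(fo[s], fo[s + m_val]),
           train_strides = cbind(start = fo[chosen], end = fo[chosen + 1L]))
    }))
    training <- assemble_training(ptrials[in_idx], plan, preprocess)
    val_traces <- lapply(seq_along(in_idx), function(i) {
      slice_trace(ptrials[[in_idx[i]]], plan[[i]]$val)
    })
    fit <- fit_with_continuation(training, val_traces, esn,
                                 config$max_validation_attempts,
                                 base_seed = seed_fold)
    for (oi in out_idx) {
      pt <- ptrials[[oi]]
      row <- if (fit$passed) {
        y <- predict_grf(fit$esn, pt$x)
        keep <- seq(min(preprocess$transient_samples + 1, length(y)),
                    length(y))
        cbind(data.frame(fold = k, trial_id = pt$trial_id, mode = pt$mode),
              report_as_row(evaluate_trial(y[keep], pt$z[keep], pt$fs,
                                           events)),
              data.frame(attempts = fit$attempts, passed = TRUE))
      } else {
        data.frame(fold = k, trial_id = pt$trial_id, mode = pt$mode,
                   epsilon = NA_real_, r2 = NA_real_, mae_fc_ms = NA_real_,
                   mae_fo_ms = NA_real_, n_matched_fc = NA_integer_,
                   n_matched_fo = NA_integer_,
                   n_unmatched_target = NA_integer_,
                   n_unmatched_pred = NA_integer_,
                   attempts = fit$attempts, passed = FALSE)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
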