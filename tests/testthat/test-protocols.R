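# Protocol tests run with a deliberately small reservoir (N = 150) and a
# small cohort so the whole file stays fast; the full-size configuration is
# exercised in test-acceptance.R.

small_esn <- function(seed = 1) esn_config(n_nodes = 150, seed = seed)

test_that("segmented splits are stride-aligned, capped and disjoint", {
  trials <- tiny_cohort(n_per_mode = 2, n_strides = 30, seed = 41)
  pts <- lapply(trials, prepare_trial)
  cfg <- protocol_config(n_repetitions = 1, strides_cap_per_trial = 10,
                         seed = 5)
  plan <- make_segmented_split(pts, cfg, seed = 5)
  plan2 <- make_segmented_split(pts, cfg, seed = 5)
  expect_identical(plan, plan2)                  # same seed, same plan

  for (i in seq_along(pts)) {
    p <- plan[[i]]
    fo <- pts[[i]]$events$foot_offs
    expect_true(p$val[1] %in% fo)                # stride-aligned window
    expect_true(p$test[2] %in% fo)
    expect_equal(p$val[2], p$test[1])
    expect_lte(nrow(p$train_strides), 10)
    # holdout covers ~50% of the strides
    n_str <- length(fo) - 1
    held <- sum(fo >= p$val[1] & fo < p$test[2])
    expect_lt(abs(held - 0.5 * n_str), 2)
    # disjointness, checked sample by sample
    hold_samples <- p$val[1]:(p$test[2] - 1)
    for (k in seq_len(nrow(p$train_strides))) {
      seg <- p$train_strides[k, 1]:(p$train_strides[k, 2] - 1)
      expect_length(intersect(seg, hold_samples), 0)
    }
  }

  few <- lapply(tiny_cohort(n_per_mode = 1, n_strides = 3, seed = 1),
                prepare_trial)
  expect_error(make_segmented_split(few, cfg, seed = 1), "too few strides")
})

test_that("training assembly applies the washout mask", {
  trials <- tiny_cohort(n_per_mode = 1, n_strides = 12, seed = 42)
  pts <- lapply(trials, prepare_trial)
  plan <- make_segmented_split(pts, protocol_config(n_repetitions = 1),
                               seed = 2)
  tr <- esngait:::assemble_training(pts, plan)
  expect_equal(length(tr$x), length(tr$z))
  for (i in seq_along(tr$x)) {
    expect_equal(ncol(tr$x[[i]]), length(tr$z[[i]]))
    expect_false(any(tr$mask[[i]][1:36]))
    expect_true(all(tr$mask[[i]][-(1:36)]))
  }
})

test_that("the continuation rule retries and reports failure states", {
  trials <- tiny_cohort(n_per_mode = 2, n_strides = 18, seed = 43)
  pts <- lapply(trials, prepare_trial)
  plan <- make_segmented_split(pts, protocol_config(n_repetitions = 1),
                               seed = 3)
  training <- esngait:::assemble_training(pts, plan)
  val <- lapply(seq_along(pts), function(i) {
    esngait:::slice_trace(pts[[i]], plan[[i]]$val)
  })
  fit <- fit_with_continuation(training, val, small_esn(), 100, base_seed = 9)
  expect_true(fit$passed)
  expect_equal(fit$attempts, 1)                  # passes on first attempt
  expect_true(all(fit$val_r2 > 0))

  none <- fit_with_continuation(training, val, small_esn(), 0)
  expect_false(none$passed)
  expect_equal(none$attempts, 0)

  # constant validation target: R2 undefined -> reported failure, no error
  broken <- val
  broken[[1]]$z[] <- 1
  bad <- fit_with_continuation(training, broken, small_esn(), 2)
  expect_false(bad$passed)
  expect_match(bad$reason, "undefined")
})

test_that("run_repetitions yields a reproducible long-format table", {
  trials <- tiny_cohort(n_per_mode = 2, n_strides = 18, seed = 44)
  pts <- lapply(trials, prepare_trial)
  cfg <- protocol_config(n_repetitions = 2, seed = 17)
  df <- run_repetitions(pts, cfg, esn = small_esn())
  expect_equal(nrow(df), 2 * 4)
  expect_setequal(unique(df$repetition), 1:2)
  df2 <- run_repetitions(pts, cfg, esn = small_esn())
  expect_identical(df, df2)                      # bit-reproducible
  expect_true(all(df$passed))
  expect_true(all(df$r2 > 0.5))
  s <- summarize_repetitions(df)
  expect_setequal(s$metric,
                  c("epsilon", "r2", "mae_fc_ms", "mae_fo_ms",
                    "n_train_strides"))
  expect_true(all(is.finite(s$mean)))
})

test_that("the training-size sweep keeps holdouts fixed and reports stride counts", {
  trials <- tiny_cohort(n_per_mode = 2, n_strides = 24, seed = 45)
  pts <- lapply(trials, prepare_trial)
  cfg <- protocol_config(n_repetitions = 2, seed = 23)
  sw <- sweep_training_fraction(pts, fractions = c(0.1, 0.5), config = cfg,
                                esn = small_esn())
  expect_equal(nrow(sw), 2)
  expect_true(all(c("fraction", "r2_mean", "r2_sd",
                    "n_train_strides_mean") %in% names(sw)))
  expect_lt(sw$n_train_strides_mean[1], sw$n_train_strides_mean[2])
  # single fraction reproduces run_repetitions
  cfg2 <- cfg; cfg2$train_fraction <- 0.5
  ref <- summarize_repetitions(run_repetitions(pts, cfg2, esn = small_esn()))
  expect_equal(sw$r2_mean[2], ref$mean[ref$metric == "r2"], tolerance = 1e-12)
})

test_that("leave-M-out folds partition the cohort", {
  ids <- sprintf("t%02d", 1:42)
  folds <- lmo_fold_plan(ids, m = 1)
  expect_length(folds, 42)
  expect_setequal(unlist(folds), ids)            # every trial once
  folds3 <- lmo_fold_plan(ids, m = 3, repetitions = 10, seed = 4)
  expect_length(folds3, 10)
  expect_true(all(vapply(folds3, length, integer(1)) == 3))
  expect_equal(anyDuplicated(vapply(folds3, paste, character(1),
                                    collapse = "|")), 0)
  expect_error(lmo_fold_plan(ids, m = 42), "smaller")
})

test_that("leave-one-out trains on held-in trials and tests the rest", {
  trials <- tiny_cohort(n_per_mode = 2, n_strides = 18, seed = 46)
  pts <- lapply(trials, prepare_trial)
  cfg <- protocol_config(n_repetitions = 1, seed = 31)
  df <- leave_m_out(pts, m = 1, config = cfg, esn = small_esn())
  expect_equal(nrow(df), 4)                      # one row per fold
  expect_setequal(df$trial_id, vapply(pts, `[[`, character(1), "trial_id"))
  expect_true(all(df$passed))
  expect_true(all(is.finite(df$r2)))
  expect_error(leave_m_out(pts, m = 4, config = cfg), "smaller")
})
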