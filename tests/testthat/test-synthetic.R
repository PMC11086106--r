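test_that("generation is deterministic in (config, patient_index)", {
  cfg <- tiny_config()
  a <- generate_patient(cfg, 1)
  b <- generate_patient(cfg, 1)
  expect_identical(a$recordings[[1]]$signal, b$recordings[[1]]$signal)
  expect_identical(vapply(a$seizures, `[[`, 0, "onset_s"),
                   vapply(b$seizures, `[[`, 0, "onset_s"))
  other <- generate_patient(tiny_config(seed = 8), 1)
  expect_false(identical(a$recordings[[1]]$signal,
                         other$recordings[[1]]$signal))
})

test_that("cohorts have distinct patients and annotated, in-span seizures", {
  cfg <- tiny_config(n_patients = 3)
  coh <- generate_cohort(cfg)
  expect_length(coh, 3)
  ids <- vapply(coh, `[[`, "", "patient_id")
  expect_false(any(duplicated(ids)))
  for (p in coh) {
    expect_equal(length(p$seizures), 2)
    spans <- recorded_spans(p)
    for (s in p$seizures)
      expect_true(any(s$onset_s >= spans$start_s & s$offset_s <= spans$end_s))
  }
})

test_that("every generated seizure passes the eligibility lookback", {
  # generator default guarantees >= 4.5 h of pre-onset recording; at test
  # scale the same invariant holds with proportionally shrunk parameters
  cfg <- tiny_config(pre_seizure_hours = 0.2)
  p <- generate_patient(cfg, 2)
  lp <- tiny_labeling()           # needs > 0.1 h + 2 min of clean lookback
  expect_equal(find_eligible_seizures(p, lp), seq_along(p$seizures))
})

test_that("a null preictal effect leaves band power indistinguishable", {
  cfg <- tiny_config(preictal_effect = 1, n_channels = 4, seed = 19,
                     pre_seizure_hours = 0.25, preictal_state_min = 5)
  p <- generate_patient(cfg, 1)
  lp <- labeling_params(preictal_min = 5, gap_hours = 0.1,
                        interictal_max_min = 5, undersample_min = 4)
  prep <- prepare_cohort_windows(list(p), lp, seed = 3)
  ws <- prep$patients[[1]]$windows
  pre <- window_band_power(subset_windows(ws, ws$labels == 1), "theta")
  int <- window_band_power(subset_windows(ws, ws$labels == 0), "theta")
  expect_gt(stats::t.test(log(pre), log(int))$p.value, 0.01)
})

test_that("a 2x amplitude effect quadruples mean band power", {
  cfg <- tiny_config(preictal_effect = 2, shared_effect_fraction = 1,
                     shared_band = "theta", n_channels = 4, seed = 23,
                     pre_seizure_hours = 0.25, preictal_state_min = 5)
  # shared fraction 1 puts the whole effect on the shared theta band
  p <- generate_patient(cfg, 1)
  lp <- labeling_params(preictal_min = 5, gap_hours = 0.1,
                        interictal_max_min = 5, undersample_min = 4)
  prep <- prepare_cohort_windows(list(p), lp, seed = 3)
  ws <- prep$patients[[1]]$windows
  pre <- window_band_power(subset_windows(ws, ws$labels == 1), "theta")
  int <- window_band_power(subset_windows(ws, ws$labels == 0), "theta")
  ratio <- mean(pre) / mean(int)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
  # alpha band untouched
  pre_a <- window_band_power(subset_windows(ws, ws$labels == 1), "alpha")
  int_a <- window_band_power(subset_windows(ws, ws$labels == 0), "alpha")
  expect_lt(mean(pre_a) / mean(int_a), 1.5)
})

test_that("shared effects transfer across patients; private ones do not", {
  lp <- tiny_labeling()
  thr_classify <- function(train_ws, test_ws) {
    # pick the most discriminative band on the training patient, then
    # threshold the test patient's log band power at the class midpoint
    bands <- names(seizcal:::.eeg_bands())
    bp <- sapply(bands, function(b) log(window_band_power(train_ws, b)))
    sep <- apply(bp, 2, function(v)
      abs(mean(v[train_ws$labels == 1]) - mean(v[train_ws$labels == 0])) /
        (stats::sd(v) + 1e-12))
    best <- bands[which.max(sep)]
    v <- bp[, best]
    thr <- (mean(v[train_ws$labels == 1]) + mean(v[train_ws$labels == 0])) / 2
    pos_hi <- mean(v[train_ws$labels == 1]) > thr
    te <- log(window_band_power(test_ws, best))
    pred <- if (pos_hi) te > thr else te < thr
    mean(pred == (test_ws$labels == 1))
  }
  accs <- function(shared_fraction, seed) {
    # leave-one-patient-out with the threshold rule: train pooled on the
    # other patients, test on the held-out one; average over targets
    cfg <- tiny_config(n_patients = 4, seizures_per_patient = 2,
                       shared_effect_fraction = shared_fraction,
                       patient_gain_spread = 1.2,
                       preictal_effect = 2.5, seed = seed)
    prep <- prepare_cohort_windows(generate_cohort(cfg), lp, seed = 2)
    ids <- names(prep$patients)
    cross <- vapply(ids, function(t) {
      tr <- bind_window_sets(lapply(prep$patients[setdiff(ids, t)],
                                    `[[`, "windows"))
      thr_classify(tr, prep$patients[[t]]$windows)
    }, 0)
    within <- vapply(ids, function(t)
      thr_classify(prep$patients[[t]]$windows,
                   prep$patients[[t]]$windows), 0)
    c(cross = mean(cross), within = mean(within))
  }
  shared <- accs(1, seed = 41)
  expect_gt(shared[["cross"]], 0.8)
  private <- accs(0, seed = 43)
  expect_lte(private[["cross"]], 0.6)
  expect_gt(private[["within"]], 0.8)
})

test_that("EDF export and re-ingest reproduce the cohort up to quantization", {
  cfg <- tiny_config(n_patients = 1, seizures_per_patient = 2,
                     n_channels = 3, pre_seizure_hours = 0.05,
                     ictal_s = c(5, 8), seed = 29)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  export_cohort(coh, dir)
  back <- import_cohort(dir)
  expect_length(back, 1)
  orig <- coh[[1]]; got <- back[[1]]
  expect_equal(length(got$recordings), length(orig$recordings))
  for (k in seq_along(orig$recordings)) {
    a <- orig$recordings[[k]]$signal
    b <- got$recordings[[k]]$signal[, seq_len(ncol(orig$recordings[[k]]$signal))]
    step <- max(apply(a, 1, function(r) diff(range(r)))) / 65535
    expect_lt(max(abs(a - b)), 2 * step)
  }
  expect_equal(vapply(got$seizures, `[[`, 0, "onset_s"),
               vapply(orig$seizures, `[[`, 0, "onset_s"), tolerance = 1e-6)
})
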