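# Orchestration tests run on a tiny synthetic cohort with the (cheap)
# gradient-boosted classifier; CNN-specific behavior is covered in
# test-cnn.R and the end-to-end study in test-acceptance.R.

prep_tiny <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_config(n_patients = 3, seizures_per_patient = 3,
                         n_channels = 4, pre_seizure_hours = 0.2,
                         shared_effect_fraction = 0.3, seed = 61)
      cache <<- prepare_cohort_windows(generate_cohort(cfg), tiny_labeling(),
                                       seed = 4)
    }
    cache
  }
})

test_that("prepared cohorts carry balanced labeled windows with provenance", {
  prep <- prep_tiny()
  expect_length(prep$patients, 3)
  for (pid in names(prep$patients)) {
    ws <- prep$patients[[pid]]$windows
    expect_equal(sum(ws$labels == 1), sum(ws$labels == 0))
    expect_true(all(ws$patient_ids == pid))
    expect_equal(dim(ws$windows)[3], 640)
  }
})

test_that("RCV folds are seed-reproducible and patient-aggregated", {
  prep <- prep_tiny()
  cls <- baseline_classifier(nrounds = 20)
  a <- run_rcv(prep, cls, k = 3, seed = 5)
  b <- run_rcv(prep, cls, k = 3, seed = 5)
  expect_equal(sapply(a$per_patient, `[[`, "acc"),
               sapply(b$per_patient, `[[`, "acc"))
  expect_setequal(names(a$per_patient), names(prep$patients))
  counts <- sapply(names(prep$patients), function(pid) {
    m <- a$per_patient[[pid]]
    m$tp + m$fp + m$tn + m$fn
  })
  expect_equal(unname(counts),
               unname(sapply(prep$patients, function(e)
                 dim(.subset2(e, "windows")$windows)[1])))
  expect_error(run_rcv(prep, cls, k = 1), "at least 2")
})

test_that("LOO excludes the target from training and from statistics", {
  prep <- prep_tiny()
  cls <- baseline_classifier(nrounds = 20)
  target <- names(prep$patients)[1]
  loo <- run_loo(prep, cls, target, seed = 2)
  expect_false(target %in% loo$provenance$train_patients)
  expect_false(target %in% loo$provenance$stats_patients)
  expect_silent(audit_leakage(loo, target))
  expect_equal(loo$metrics$tp + loo$metrics$fp + loo$metrics$tn +
                 loo$metrics$fn,
               dim(prep$patients[[target]]$windows$windows)[1])
  expect_error(run_loo(prep, cls, "nope"), "unknown patient")
})

test_that("single-seizure patients train but cannot be leave-out targets", {
  cfg <- tiny_config(n_patients = 2, seizures_per_patient = 1,
                     pre_seizure_hours = 0.2, seed = 62)
  # indices 4 and 5 so the ids don't collide with prep_tiny's sim01..sim03
  solo <- prepare_cohort_windows(list(generate_patient(cfg, 4),
                                      generate_patient(cfg, 5)),
                                 tiny_labeling(), seed = 1)
  prep <- prep_tiny()
  merged <- prep
  merged$patients <- c(prep$patients, solo$patients)
  cls <- baseline_classifier(nrounds = 20)
  target <- names(prep$patients)[1]
  loo <- run_loo(merged, cls, target, seed = 3)
  expect_true(all(names(solo$patients) %in% loo$provenance$train_patients))
  expect_error(run_loo(merged, cls, names(solo$patients)[1]),
               "single seizure")
})

test_that("calibration bookkeeping holds out the right seizures", {
  prep <- prep_tiny()
  cls <- baseline_classifier(nrounds = 20)
  target <- names(prep$patients)[1]
  loo <- run_loo(prep, cls, target, seed = 2)
  paired <- prep$patients[[target]]$seizures$seizure_index
  cal1 <- run_calibration(prep, cls, target, loo, n_cal_seizures = 1,
                          seed = 9)
  expect_equal(cal1$cal_seizures, min(paired))
  expect_setequal(cal1$provenance$test_seizures,
                  setdiff(paired, min(paired)))
  cal2 <- run_calibration(prep, cls, target, loo, n_cal_seizures = 2,
                          seed = 9)
  expect_length(cal2$cal_seizures, 2)
  expect_length(cal2$provenance$test_seizures, 1)
  expect_silent(audit_leakage(cal2, target))
  # reproducible second-seizure draw
  cal2b <- run_calibration(prep, cls, target, loo, n_cal_seizures = 2,
                           seed = 9)
  expect_equal(cal2$cal_seizures, cal2b$cal_seizures)
})

test_that("calibration refuses to consume every labeled seizure", {
  cfg <- tiny_config(n_patients = 1, seizures_per_patient = 2,
                     pre_seizure_hours = 0.2, seed = 63)
  # index 4 so the id doesn't collide with prep_tiny's sim01..sim03
  prep2 <- prepare_cohort_windows(list(generate_patient(cfg, 4)),
                                  tiny_labeling(), seed = 1)
  prep <- prep_tiny()
  merged <- prep
  merged$patients <- c(prep$patients, prep2$patients)
  cls <- baseline_classifier(nrounds = 20)
  target <- names(prep2$patients)[1]
  loo <- run_loo(merged, cls, target, seed = 1)
  cal1 <- run_calibration(merged, cls, target, loo, 1, seed = 1)
  expect_length(cal1$provenance$test_seizures, 1)
  expect_error(run_calibration(merged, cls, target, loo, 2, seed = 1),
               "no labeled seizure")
})

test_that("leakage audit detects contaminated provenance", {
  fake <- list(provenance = list(train_patients = c("a", "b"),
                                 stats_patients = c("a", "b"),
                                 cal_seizures = integer(0)))
  expect_error(audit_leakage(fake, "a"), "leakage")
  ok <- list(provenance = list(train_patients = "b", stats_patients = "b",
                               cal_seizures = integer(0)))
  expect_silent(audit_leakage(ok, "a"))
})

test_that("the suite assembles a per-patient condition table with statistics", {
  prep <- prep_tiny()
  cls <- baseline_classifier(nrounds = 20)
  suite <- run_experiment_suite(prep, cls, k = 3, seed = 8)
  expect_s3_class(suite, "experiment_suite")
  expect_setequal(unique(suite$table$condition),
                  c("RCV", "LOO", "Cal1", "Cal2"))
  expect_setequal(unique(suite$table$metric), c("ACC", "SEN", "SPE"))
  acc <- suite$wide$ACC
  expect_true(all(c("RCV", "LOO", "Cal1", "Cal2") %in% colnames(acc)))
  expect_false(is.null(suite$anova$ACC))
  expect_equal(suite$anova$ACC$df_condition, 2)
  expect_equal(nrow(suite$tukey$ACC), 3)
})
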