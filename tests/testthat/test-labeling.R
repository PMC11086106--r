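test_that("eligibility requires the full lookback of clean recorded time", {
  # 5 h before onset: more than the 4 h 15 min needed
  expect_equal(find_eligible_seizures(toy_patient(5)), 1L)
  # 3 h before onset: not enough
  expect_equal(find_eligible_seizures(toy_patient(3)), integer(0))
  # just over the boundary: 4 h 15 min + 1 min
  expect_equal(find_eligible_seizures(toy_patient(4.25 + 1 / 60)), 1L)
  # an earlier seizure ending at 5.5 h contaminates a 6 h onset's lookback
  p <- toy_patient(c(5.49, 6), dur_h = 6.5)
  expect_false(2L %in% find_eligible_seizures(p))
  expect_true(1L %in% find_eligible_seizures(p))
})

test_that("patient-level leave-out eligibility needs two seizures", {
  expect_false(patient_eligible_for_leaveout(toy_patient(5)))
  expect_true(patient_eligible_for_leaveout(toy_patient(c(5, 10), dur_h = 11)))
})

test_that("labeling arithmetic matches the segmentation rules", {
  # onset at 5 h, recording from 0: only 45 of the max 60 interictal
  # minutes exist before the 4-h buffer
  lab <- label_seizure(toy_patient(5), 1)
  expect_equal(lab$preictal$start_s, 4.75 * 3600)
  expect_equal(lab$preictal$end_s, 5 * 3600)
  expect_equal(lab$interictal$end_s, 0.75 * 3600)
  expect_equal(lab$interictal$start_s, 0)
  # onset at 10 h: the full 60 minutes
  lab <- label_seizure(toy_patient(10), 1)
  expect_equal(lab$preictal$start_s, 9.75 * 3600)
  expect_equal(lab$interictal$start_s, 4.75 * 3600)
  expect_equal(lab$interictal$end_s, 5.75 * 3600)
  # onset at 4 h 16 min: a 1-minute interictal remains valid
  lab <- label_seizure(toy_patient(4 + 16 / 60), 1)
  expect_equal(lab$interictal$end_s - lab$interictal$start_s, 60)
  # preictal ends exactly at onset; buffer is exact by construction
  expect_equal(lab$preictal$end_s, (4 + 16 / 60) * 3600)
  expect_equal(lab$preictal$start_s - lab$interictal$end_s, 4 * 3600)
})

test_that("an earlier seizure truncates the interictal window", {
  # onset 10 h; earlier seizure ends at 4.8 h, inside the candidate
  # interictal window [4.75, 5.75] -> truncated to start at 4.8... but the
  # lookback rule measures clean time from the later boundary, so the
  # interictal shrinks accordingly
  p <- toy_patient(c(4.79, 10), dur_h = 10.5)
  lab <- label_seizure(p, 2)
  expect_gte(lab$interictal$start_s, 4.79 * 3600 + 40)  # after prior offset
  expect_equal(lab$interictal$end_s, 5.75 * 3600)
})

test_that("undersampling draws a uniform contiguous sub-segment", {
  seg <- segment("p", "interictal", 0, 3600, 1L)
  a <- undersample_interictal(seg, seed = 9)
  b <- undersample_interictal(seg, seed = 9)
  expect_equal(a$start_s, b$start_s)
  expect_equal(a$end_s - a$start_s, 900)
  expect_gte(a$start_s, 0)
  expect_lte(a$end_s, 3600)
  short <- segment("p", "interictal", 0, 600, 1L)
  expect_warning(out <- undersample_interictal(short), "unchanged")
  expect_equal(out$end_s, 600)
  expect_error(
    undersample_interictal(segment("p", "preictal", 0, 900, 1L)),
    "interictal")
  # empirical start distribution uniform on [0, 45] min
  starts <- vapply(seq_len(1000), function(s)
    undersample_interictal(seg, seed = s)$start_s, 0)
  ks <- stats::ks.test(starts, "punif", 0, 2700)
  expect_gt(ks$p.value, 0.01)
})

test_that("labeled pairs keep the exact buffer and balanced durations", {
  p <- toy_patient(c(6, 12), dur_h = 12.5)
  df <- label_cohort(list(p))
  expect_equal(nrow(df), 4)
  for (i in unique(df$seizure_index)) {
    pre <- df[df$seizure_index == i & df$label == "preictal", ]
    int <- df[df$seizure_index == i & df$label == "interictal", ]
    expect_lte(int$end_s, pre$start_s - 4 * 3600)
    expect_equal(pre$end_s - pre$start_s, 900)
    expect_equal(int$end_s - int$start_s, 900)
    # no intersection with any ictal interval
    for (s in p$seizures) {
      expect_true(pre$end_s <= s$onset_s || pre$start_s >= s$offset_s)
      expect_true(int$end_s <= s$onset_s || int$start_s >= s$offset_s)
    }
  }
})
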