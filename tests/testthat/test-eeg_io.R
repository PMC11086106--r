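test_that("EDF write-then-read is identity up to 16-bit quantization", {
  rec <- sine_recording(c(5, 11), sr = 256, dur_s = 10, amp = 80)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path, patient_id = rec$patient_id)
  expect_identical(dim(back$signal), c(2L, 2560L))
  expect_equal(back$sample_rate_hz, 256)
  expect_equal(back$channel_names, rec$channel_names)
  # quantization step = physical range / 65535
  for (i in 1:2) {
    step <- diff(range(rec$signal[i, ])) / 65535
    expect_lt(max(abs(back$signal[i, ] - rec$signal[i, ])), step)
  }
})

test_that("EDF reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeBin(as.raw(rep(32, 100)), path)          # truncated header
  expect_error(read_edf(path), "truncated header")
  # header declaring zero signals
  rec <- sine_recording(1, dur_s = 2)
  write_edf(rec, path)
  raw <- readBin(path, "raw", file.size(path))
  raw[253:256] <- charToRaw("0   ")
  writeBin(raw, path)
  expect_error(read_edf(path), "zero signals")
  expect_error(read_edf("/nonexistent/file.edf"), "does not exist")
})

test_that("reader converts physical units to microvolts", {
  rec <- sine_recording(5, dur_s = 2, amp = 1)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  raw <- readBin(path, "raw", file.size(path))
  # patch the physical-dimension field of signal 1 from uV to mV
  at <- 256 + 16 + 80
  raw[(at + 1):(at + 8)] <- charToRaw(sprintf("%-8s", "mV"))
  writeBin(raw, path)
  back <- read_edf(path)
  expect_equal(max(back$signal), 1000 * max(rec$signal), tolerance = 1e-3)
})

test_that("channel selection returns requested channels in order, idempotently", {
  rec <- noise_recording(n_ch = 6)
  sel <- select_common_channels(rec, c("CH5", "CH2", "CH3"))
  expect_equal(sel$channel_names, c("CH5", "CH2", "CH3"))
  expect_equal(sel$signal[1, ], rec$signal[5, ])
  twice <- select_common_channels(sel, c("CH5", "CH2", "CH3"))
  expect_identical(twice$signal, sel$signal)
  ident <- select_common_channels(rec, rec$channel_names)
  expect_identical(ident$signal, rec$signal)
  expect_error(select_common_channels(rec, c("CH1", "NOPE")), "NOPE")
})

test_that("summary-dialect annotations parse onto the patient timeline", {
  txt <- c("File Name: a.edf",
           "Number of Seizures in File: 1",
           "Seizure Start Time: 2996 seconds",
           "Seizure End Time: 3036 seconds",
           "File Name: b.edf",
           "Seizure 1 Start Time: 100 seconds",
           "Seizure 1 End Time: 150 seconds")
  ev <- parse_seizure_annotations(txt, c(a.edf = 0, b.edf = 3600))
  expect_length(ev, 2)
  expect_equal(ev[[1]]$onset_s, 2996)
  expect_equal(ev[[1]]$offset_s, 3036)
  expect_equal(ev[[2]]$onset_s, 3700)
  expect_equal(ev[[2]]$offset_s, 3750)
})

test_that("CSV sidecar annotations parse with offsets and validation", {
  csv <- c("file,onset_s,offset_s", "a.edf,10,20", "b.edf,5,9")
  ev <- parse_seizure_annotations(csv, c(a.edf = 0, b.edf = 1000))
  expect_equal(vapply(ev, `[[`, 0, "onset_s"), c(10, 1005))
  bad <- c("File Name: a.edf",
           "Seizure 1 Start Time: 50 seconds",
           "Seizure 1 End Time: 40 seconds")
  expect_error(parse_seizure_annotations(bad, c(a.edf = 0)), "line 3")
  expect_error(
    parse_seizure_annotations(c("file,onset_s,offset_s", "zz.edf,1,2"),
                              c(a.edf = 0)),
    "absent from the cohort")
})

test_that("cohort assembly rejects seizures outside recorded spans", {
  rec1 <- noise_recording(dur_s = 100, start_offset_s = 0)
  rec2 <- noise_recording(dur_s = 100, start_offset_s = 200, seed = 2)
  expect_error(
    patient_record("p", list(rec1, rec2),
                   list(seizure_event(150, 160))),   # falls in the gap
    "outside recorded time")
  p <- patient_record("p", list(rec1, rec2), list(seizure_event(250, 260)))
  expect_equal(length(p$seizures), 1)
  overlap <- noise_recording(dur_s = 100, start_offset_s = 50, seed = 3)
  expect_error(patient_record("p", list(rec1, overlap)), "overlap")
})
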