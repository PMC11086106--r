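test_that("preprocessing halves the rate and preserves duration", {
  rec <- noise_recording(n_ch = 2, sr = 256, dur_s = 60)
  out <- preprocess_recording(rec)
  expect_equal(out$sample_rate_hz, 128)
  expect_equal(ncol(out$signal), 7680)
  expect_equal(recording_duration(out), 60)
  expect_error(preprocess_recording(noise_recording(sr = 128)),
               "unsupported sample rate")
})

test_that("the 50 Hz notch attenuates power-line interference by >= 20 dB", {
  rec <- sine_recording(50, sr = 256, dur_s = 20, amp = 50)
  out <- preprocess_recording(rec)
  drop_edges <- 128:(ncol(out$signal) - 128)   # ignore boundary transients
  rms_out <- sqrt(mean(out$signal[1, drop_edges]^2))
  rms_in <- sqrt(mean(rec$signal[1, ]^2))
  expect_lt(rms_out / rms_in, 0.10)
})

test_that("the high-pass removes a constant offset", {
  rec <- noise_recording(n_ch = 2, sr = 256, dur_s = 30, sd = 10)
  rec$signal <- rec$signal + 100
  out <- preprocess_recording(rec)
  expect_lt(max(abs(rowMeans(out$signal))), 1)
})

test_that("in-band content survives preprocessing", {
  rec <- sine_recording(10, sr = 256, dur_s = 20, amp = 50)
  out <- preprocess_recording(rec)
  mid <- out$signal[1, 500:2000]
  expect_gt(sqrt(mean(mid^2)), 0.8 * 50 / sqrt(2))
})

test_that("windowing is non-overlapping and left-aligned with remainder drop", {
  rec <- noise_recording(n_ch = 3, sr = 256, dur_s = 1000)
  proc <- preprocess_recording(rec)
  ws <- segment_to_windows(proc, segment("noise", "preictal", 0, 900, 1L))
  expect_equal(dim(ws$windows), c(180L, 3L, 640L))
  expect_equal(sum(ws$labels), 180L)
  # windows reproduce the underlying signal without overlap
  expect_equal(ws$windows[2, 1, ], proc$signal[1, 641:1280])
  ws2 <- segment_to_windows(proc, segment("noise", "interictal", 0, 12, 1L))
  expect_equal(dim(ws2$windows)[1], 2L)
  expect_equal(sum(ws2$labels), 0L)
  expect_warning(
    ws3 <- segment_to_windows(proc, segment("noise", "preictal", 0, 4, 1L)),
    "shorter than one window")
  expect_equal(dim(ws3$windows)[1], 0L)
  expect_error(
    segment_to_windows(proc, segment("noise", "preictal", 900, 1100, 1L)),
    "does not lie within")
})

test_that("a labeled pair yields balanced 180 + 180 windows", {
  p <- toy_patient(6, dur_h = 6.2, sr = 256)
  lab <- label_seizure(p, 1)
  inter <- undersample_interictal(lab$interictal, seed = 1)
  proc <- preprocess_recording(p$recordings[[1]])
  wpre <- segment_to_windows(proc, lab$preictal)
  wint <- segment_to_windows(proc, inter)
  expect_equal(dim(wpre$windows)[1], 180L)
  expect_equal(dim(wint$windows)[1], 180L)
})

test_that("channel statistics floor dead channels and are per-channel", {
  rec <- recording(rbind(rep(5, 1000), rnorm(1000, 10, 2)), 128,
                   c("A", "B"))
  st <- compute_channel_stats(rec)
  expect_equal(st$means[1], 5)
  expect_equal(st$stds[1], 1e-6)
  expect_gt(st$stds[2], 1)
  big <- recording(matrix(rnorm(1e5), 1), 128, "A")
  st2 <- compute_channel_stats(big)
  expect_equal(st2$means[1], 0, tolerance = 0.02)
  expect_equal(st2$stds[1], 1, tolerance = 0.02)
  empty <- window_set(array(0, c(0, 2, 640)), integer(0), character(0),
                      integer(0), 128, 5)
  expect_error(compute_channel_stats(empty), "empty")
})

test_that("standardization centers and scales, and refuses double application", {
  ws <- segment_to_windows(noise_recording(n_ch = 2, sr = 256, dur_s = 100,
                                           sd = 30) |> preprocess_recording(),
                           segment("noise", "preictal", 0, 90, 1L))
  st <- compute_channel_stats(ws)
  z <- standardize(ws, st)
  for (c in 1:2) {
    v <- as.numeric(z$windows[, c, ])
    expect_equal(mean(v), 0, tolerance = 1e-8)
    expect_equal(sd(v), 1, tolerance = 1e-2)
  }
  expect_error(standardize(z, st), "twice")
  bad <- compute_channel_stats(
    segment_to_windows(noise_recording(n_ch = 3, sr = 256, dur_s = 20) |>
                         preprocess_recording(),
                       segment("noise", "preictal", 0, 15, 1L)))
  expect_error(standardize(ws, bad), "channel mismatch")
})

test_that("pooled statistics weight patients equally", {
  s1 <- structure(list(means = c(0, 0), stds = c(1, 2),
                       provenance = "per-patient:a"), class = "channel_stats")
  s2 <- structure(list(means = c(10, 4), stds = c(3, 2),
                       provenance = "per-patient:b"), class = "channel_stats")
  pooled <- pool_channel_stats(list(s1, s2))
  expect_equal(pooled$means, c(5, 2))
  expect_equal(pooled$stds, c(sqrt(5), 2))   # root-mean-square of stds
  expect_equal(pooled$provenance, "pooled-train")
})
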