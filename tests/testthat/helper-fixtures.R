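# Shared fixtures: tiny recordings, patients and cohorts built in code.

# sinusoid recording: one row per frequency (Hz), amplitude in microvolts
sine_recording <- function(freqs, sr = 256, dur_s = 10, amp = 50,
                           patient_id = "sine", start_offset_s = 0) {
  t <- seq(0, dur_s - 1 / sr, by = 1 / sr)
  sig <- t(sapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  recording(sig, sr, paste0("CH", seq_along(freqs)), patient_id,
            start_offset_s)
}

noise_recording <- function(n_ch = 2, sr = 256, dur_s = 10, sd = 20,
                            patient_id = "noise", start_offset_s = 0,
                            seed = 1) {
  withr::with_seed(seed, {
    sig <- matrix(stats::rnorm(n_ch * sr * dur_s, sd = sd), n_ch)
    recording(sig, sr, paste0("CH", seq_len(n_ch)), patient_id,
              start_offset_s)
  })
}

# a patient with one long recording and seizures at given onsets (hours)
toy_patient <- function(onsets_h, dur_h = max(onsets_h) + 0.5,
                        ictal_s = 40, sr = 16, n_ch = 2, id = "toy") {
  sig <- matrix(0, n_ch, as.integer(dur_h * 3600 * sr))
  rec <- recording(sig, sr, paste0("CH", seq_len(n_ch)), id)
  seiz <- lapply(onsets_h, function(h)
    seizure_event(h * 3600, h * 3600 + ictal_s))
  patient_record(id, list(rec), seiz)
}

# scaled-down generator settings used across synthetic tests: short
# pre-seizure stretches with correspondingly shrunk labeling windows
tiny_labeling <- function() labeling_params(preictal_min = 2,
                                            gap_hours = 0.1,
                                            interictal_max_min = 5,
                                            undersample_min = 2)

tiny_config <- function(...) {
  # preictal_state_min shrinks with the pre-seizure span so the simulated
  # preictal state never reaches back into the interictal window
  defaults <- list(n_patients = 2, seizures_per_patient = 2, n_channels = 4,
                   pre_seizure_hours = 0.2, preictal_effect = 2,
                   preictal_state_min = 4,
                   shared_effect_fraction = 0.5, seed = 7)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# mean band power of each 5-s window of a segment, for a named band
window_band_power <- function(ws, band) {
  n <- dim(ws$windows)[1]
  vapply(seq_len(n), function(i) {
    x <- colMeans(ws$windows[i, , , drop = TRUE])
    band_power(x, ws$sample_rate_hz)[[band]]
  }, 0)
}
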