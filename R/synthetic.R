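#' Synthetic cohort configuration
#'
#' Describes a cohort of simulated scalp-EEG patients. Each patient's
#' interictal signal is a mixture of band-limited Gaussian noise in the
#' canonical delta/theta/alpha/beta/gamma bands, scaled by patient-specific
#' per-band gains (spectral signatures), with a shared across-channel
#' component so interchannel correlations exist, plus a white noise floor.
#' During the `preictal_state_min` minutes before each seizure onset, the
#' amplitude of designated bands is multiplied by `preictal_effect`: one
#' globally shared band (`shared_band`) carries a fraction
#' `shared_effect_fraction` of the effect (on a log scale) and a
#' patient-specific band carries the remainder. With the fraction at 1 the
#' preictal signature transfers across patients (leave-one-patient-out is
#' learnable); at 0 it is fully patient-specific (cross-patient transfer
#' fails, and calibration on the target patient's own seizures is what
#' recovers performance). Ictal spans carry a high-amplitude 3 Hz marker so
#' they can never be silently mislabeled as background.
#'
#' @param n_patients number of patients.
#' @param seizures_per_patient a count, or a `c(min, max)` range sampled per
#'   patient.
#' @param n_channels channels per recording (default 20).
#' @param sample_rate_hz sampling rate (default 256).
#' @param pre_seizure_hours hours of contiguous recording before each
#'   seizure onset (default 4.5, comfortably beyond the 4 h 15 min
#'   eligibility lookback).
#' @param band_edges_hz named list of band edges in Hz.
#' @param patient_gain_spread multiplicative spread of per-patient band
#'   gains (gain drawn log-uniform in `[1/spread, spread]` times the band's
#'   base amplitude).
#' @param preictal_effect amplitude multiplier applied to designated bands
#'   in the preictal state (power scales with its square).
#' @param shared_effect_fraction fraction (0..1) of the log-effect applied
#'   to the shared band; the rest goes to the patient-specific band.
#' @param shared_band name of the globally shared effect band.
#' @param preictal_state_min length of the generator's preictal state in
#'   minutes (default 15).
#' @param seizure_gain_jitter multiplicative spread of per-seizure band-gain
#'   wobble (log-uniform in `[1/jitter, jitter]`, drawn per recording and
#'   band). Models within-patient variability between seizure events: a
#'   model calibrated on one seizure faces slightly different spectra on the
#'   next, and averaging two calibration seizures helps. 1 disables it.
#' @param noise_floor white-noise amplitude in microvolts.
#' @param channel_mixing variance fraction of the across-channel shared
#'   component (default 0.5).
#' @param ictal_s `c(min, max)` ictal duration range in seconds.
#' @param seed integer master seed; all per-patient randomness derives from
#'   it deterministically.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 8, seizures_per_patient = c(2, 4),
                             n_channels = 20, sample_rate_hz = 256,
                             pre_seizure_hours = 4.5,
                             band_edges_hz = NULL,
                             patient_gain_spread = 2,
                             preictal_effect = 2,
                             shared_effect_fraction = 0.3,
                             shared_band = "theta",
                             preictal_state_min = 15,
                             seizure_gain_jitter = 1.2,
                             noise_floor = 2,
                             channel_mixing = 0.5,
                             ictal_s = c(30, 60),
                             seed = 1) {
  if (is.null(band_edges_hz)) band_edges_hz <- .eeg_bands()
  stopifnot(n_patients >= 1, n_channels >= 1, sample_rate_hz > 0,
            pre_seizure_hours > 0, patient_gain_spread >= 1,
            preictal_effect > 0,
            shared_effect_fraction >= 0, shared_effect_fraction <= 1,
            shared_band %in% names(band_edges_hz),
            preictal_state_min > 0, seizure_gain_jitter >= 1,
            noise_floor >= 0,
            channel_mixing >= 0, channel_mixing <= 1)
  if (length(seizures_per_patient) == 1)
    seizures_per_patient <- rep(seizures_per_patient, 2)
  stopifnot(seizures_per_patient[1] >= 1,
            seizures_per_patient[2] >= seizures_per_patient[1])
  structure(list(n_patients = as.integer(n_patients),
                 seizures_per_patient = as.integer(seizures_per_patient),
                 n_channels = as.integer(n_channels),
                 sample_rate_hz = sample_rate_hz,
                 pre_seizure_hours = pre_seizure_hours,
                 band_edges_hz = band_edges_hz,
                 patient_gain_spread = patient_gain_spread,
                 preictal_effect = preictal_effect,
                 shared_effect_fraction = shared_effect_fraction,
                 shared_band = shared_band,
                 preictal_state_min = preictal_state_min,
                 seizure_gain_jitter = seizure_gain_jitter,
                 noise_floor = noise_floor,
                 channel_mixing = channel_mixing,
                 ictal_s = ictal_s,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# per-band base amplitudes in microvolts (roughly 1/f, scalp-typical)
.band_base_amp <- function(bands) {
  base <- c(delta = 20, theta = 12, alpha = 10, beta = 5, gamma = 3)
  amp <- base[names(bands)]
  amp[is.na(amp)] <- 5
  names(amp) <- names(bands)
  amp
}

# deterministic sub-seed per patient, kept below 2^31
.patient_seed <- function(config, patient_index) {
  as.integer((as.numeric(config$seed) * 7919 + patient_index * 104729) %%
               .Machine$integer.max)
}

#' Generate one synthetic patient
#'
#' One recording per seizure, each with `pre_seizure_hours` of contiguous
#' pre-onset signal, the ictal span, and a short tail; recordings are
#' separated by 60-second unrecorded gaps on the patient timeline.
#' Deterministic in `(config, patient_index)`.
#'
#' @param config a `synthetic_config`.
#' @param patient_index 1-based patient number.
#' @return A `seiz_patient` with annotated seizures.
#' @export
generate_patient <- function(config, patient_index) {
  stopifnot(inherits(config, "synthetic_config"))
  pseed <- .patient_seed(config, patient_index)
  bands <- config$band_edges_hz
  nb <- length(bands)
  sr <- config$sample_rate_hz
  shared_idx <- match(config$shared_band, names(bands))

  draws <- withr::with_seed(pseed, {
    rng_sz <- config$seizures_per_patient
    n_seiz <- if (rng_sz[1] == rng_sz[2]) rng_sz[1] else
      sample(seq(rng_sz[1], rng_sz[2]), 1)
    spread <- log(config$patient_gain_spread)
    gains_mult <- matrix(exp(stats::runif(config$n_channels * nb,
                                          -spread, spread)),
                         config$n_channels, nb)
    ictal_len <- stats::runif(n_seiz, config$ictal_s[1], config$ictal_s[2])
    rec_seeds <- sample.int(.Machine$integer.max - 1, n_seiz)
    jit <- log(config$seizure_gain_jitter)
    jitter <- matrix(exp(stats::runif(n_seiz * nb, -jit, jit)), n_seiz, nb)
    list(n_seiz = n_seiz, gains_mult = gains_mult,
         ictal_len = ictal_len, rec_seeds = rec_seeds, jitter = jitter)
  })
  # patient-specific bands are assigned round-robin over the non-shared
  # bands, so even small cohorts get maximally dispersed preictal
  # signatures: with random assignment, band collisions between patients
  # would reintroduce cross-patient transfer that the shared fraction is
  # supposed to control
  others <- setdiff(seq_len(nb), shared_idx)
  own_up <- others[(patient_index - 1) %% length(others) + 1]
  own_down <- others[patient_index %% length(others) + 1]

  base_amp <- .band_base_amp(bands)
  gains <- sweep(draws$gains_mult, 2, base_amp, `*`)
  # split the log-effect between the shared band and a patient-specific
  # redistribution: one private band is amplified and another attenuated by
  # the same factor, so the patient-specific part of the preictal state
  # changes spectral composition without a universal total-power cue that
  # any cross-patient model could exploit
  effect <- rep(1, nb)
  effect[shared_idx] <- config$preictal_effect ^ config$shared_effect_fraction
  own <- config$preictal_effect ^ (1 - config$shared_effect_fraction)
  effect[own_up] <- effect[own_up] * own
  effect[own_down] <- effect[own_down] / own

  nyq <- sr / 2
  coefs <- lapply(bands, function(e)
    signal::butter(2, pmin(c(e[1], e[2]) / nyq, 0.99), type = "pass"))

  pre_s <- config$pre_seizure_hours * 3600
  tail_s <- 10
  recs <- vector("list", draws$n_seiz)
  seizures <- vector("list", draws$n_seiz)
  offset <- 0
  for (k in seq_len(draws$n_seiz)) {
    ict <- draws$ictal_len[k]
    dur_s <- ceiling(pre_s + ict + tail_s)
    L <- as.integer(dur_s * sr)
    sig <- .synth_recording(
      config$n_channels, L,
      lapply(coefs, `[[`, "b"), lapply(coefs, `[[`, "a"),
      sweep(gains, 2, draws$jitter[k, ], `*`),
      config$channel_mixing, config$noise_floor, effect,
      (pre_s - config$preictal_state_min * 60) * sr, pre_s * sr,
      pre_s * sr, (pre_s + ict) * sr,
      ictal_amp = 150, sample_rate = sr,
      seed = draws$rec_seeds[k])
    recs[[k]] <- recording(sig, sr, sprintf("SYN%02d", seq_len(config$n_channels)),
                           patient_id = sprintf("sim%02d", patient_index),
                           start_offset_s = offset)
    seizures[[k]] <- seizure_event(offset + pre_s, offset + pre_s + ict)
    offset <- offset + dur_s + 60          # unrecorded gap between files
  }
  patient_record(sprintf("sim%02d", patient_index), recs, seizures,
                 gender = if (patient_index %% 2) "f" else "m")
}

#' Generate a synthetic cohort
#'
#' @param config a `synthetic_config`.
#' @return list of `seiz_patient`, one per patient, with distinct ids.
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(config$n_patients), function(i) generate_patient(config, i))
}

#' Export a cohort to EDF files with a CSV annotation sidecar
#'
#' Writes one EDF per recording (`<patient>_r<k>.edf`), an
#' `annotations.csv` sidecar (`file,onset_s,offset_s`, in-file seconds) and
#' a `channels.txt` listing the common channel names.
#'
#' @param cohort list of `seiz_patient`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the annotation data.frame.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- list()
  for (p in cohort) {
    spans <- recorded_spans(p)
    for (k in seq_along(p$recordings)) {
      fname <- sprintf("%s_r%d.edf", p$patient_id, k)
      write_edf(p$recordings[[k]], file.path(dir, fname))
      for (s in p$seizures) {
        if (s$onset_s >= spans$start_s[k] - 1e-9 &&
            s$offset_s <= spans$end_s[k] + 1e-9)
          ann[[length(ann) + 1]] <- data.frame(
            file = fname, onset_s = s$onset_s - spans$start_s[k],
            offset_s = s$offset_s - spans$start_s[k])
      }
    }
  }
  ann <- do.call(rbind, ann)
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  writeLines(cohort[[1]]$recordings[[1]]$channel_names,
             file.path(dir, "channels.txt"))
  invisible(ann)
}

#' Import a cohort previously written by [export_cohort()]
#'
#' @param dir directory containing the EDF files and `annotations.csv`.
#' @return list of `seiz_patient`.
#' @export
import_cohort <- function(dir) {
  ann_path <- file.path(dir, "annotations.csv")
  stopifnot(file.exists(ann_path))
  files <- sort(list.files(dir, pattern = "\\.edf$"))
  pids <- sub("_r\\d+\\.edf$", "", files)
  out <- list()
  for (pid in unique(pids)) {
    pf <- files[pids == pid]
    ord <- order(as.integer(sub(".*_r(\\d+)\\.edf$", "\\1", pf)))
    pf <- pf[ord]
    offset <- 0
    recs <- list(); offsets <- numeric()
    for (f in pf) {
      r <- read_edf(file.path(dir, f), patient_id = pid,
                    start_offset_s = offset)
      recs[[length(recs) + 1]] <- r
      offsets <- c(offsets, offset)
      names(offsets)[length(offsets)] <- f
      offset <- offset + recording_duration(r) + 60
    }
    # keep only this patient's events (sidecar covers the whole cohort)
    ann <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
    keep <- ann$file %in% pf
    events <- parse_seizure_annotations(
      c("file,onset_s,offset_s",
        sprintf("%s,%s,%s", ann$file[keep], ann$onset_s[keep],
                ann$offset_s[keep])),
      file_offsets = offsets)
    out[[length(out) + 1]] <- patient_record(pid, recs, events)
  }
  out
}
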