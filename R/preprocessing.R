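#' Preprocess a recording
#'
#' Fixed pipeline applied to the continuous signal before any windowing:
#' notch filters at 50 and 100 Hz (power-line interference), a zero-phase
#' 4th-order Butterworth high-pass at 1 Hz (DC and baseline drift), a
#' low-pass at 125 Hz, then decimation from 256 Hz to 128 Hz behind the
#' decimator's own anti-alias low-pass, which governs the final band (the
#' 125 Hz low-pass is above the post-decimation Nyquist of 64 Hz and is
#' retained for fidelity to the published chain, not for band control).
#' All filtering happens at the native rate on whole recordings — never on
#' individual windows — so no window carries filter edge transients.
#' Filters are designed with `signal::butter` (plus a standard second-order
#' notch biquad) and applied by the package's compiled direct-form-II
#' routines, which keep hour-scale multichannel recordings fast to process.
#'
#' @param rec a `seiz_recording` sampled at 256 Hz or above; the rate must
#'   be an integer multiple of `target_rate_hz`.
#' @param target_rate_hz output rate (default 128).
#' @return A preprocessed `seiz_recording` at `target_rate_hz`.
#' @export
preprocess_recording <- function(rec, target_rate_hz = 128) {
  stopifnot(inherits(rec, "seiz_recording"))
  sr <- rec$sample_rate_hz
  if (sr < 256)
    stop("unsupported sample rate ", sr,
         " Hz: preprocessing expects recordings at 256 Hz or above")
  q <- sr / target_rate_hz
  if (abs(q - round(q)) > 1e-9)
    stop("sample rate ", sr, " Hz is not an integer multiple of the ",
         target_rate_hz, " Hz target")
  q <- as.integer(round(q))
  nyq <- sr / 2
  hp <- signal::butter(4, 1 / nyq, type = "high")
  lp <- signal::butter(4, min(125, 0.95 * nyq) / nyq, type = "low")
  aa <- signal::butter(8, 0.9 * (target_rate_hz / 2) / nyq, type = "low")
  n50 <- .notch_biquad(50, sr, q = 30)
  n100 <- if (nyq > 100) .notch_biquad(100, sr, q = 30) else NULL
  n_out <- ncol(rec$signal) %/% q
  out <- matrix(0, nrow(rec$signal), n_out)
  for (i in seq_len(nrow(rec$signal))) {
    x <- rec$signal[i, ]
    x <- .iir_filtfilt(n50$b, n50$a, x)
    if (!is.null(n100)) x <- .iir_filtfilt(n100$b, n100$a, x)
    x <- .iir_filtfilt(hp$b, hp$a, x)
    x <- .iir_filtfilt(lp$b, lp$a, x)
    x <- .iir_filtfilt(aa$b, aa$a, x)
    out[i, ] <- x[seq(1, n_out * q, by = q)]
  }
  recording(out, target_rate_hz, rec$channel_names, rec$patient_id,
            rec$start_offset_s)
}

# second-order IIR notch (standard RBJ biquad), quality factor q
.notch_biquad <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Cut a labeled segment into fixed-length windows
#'
#' Non-overlapping, left-aligned windows; a trailing remainder shorter than
#' `window_s` is discarded. Overlap is deliberately not supported: overlapping
#' windows would place near-duplicate samples on both sides of random
#' cross-validation splits.
#'
#' @param rec a preprocessed `seiz_recording`.
#' @param seg a `seiz_segment` lying within the recording.
#' @param window_s window length in seconds (default 5).
#' @return A `window_set` (see [window_set()]); empty, with a warning, if the
#'   segment is shorter than one window.
#' @export
segment_to_windows <- function(rec, seg, window_s = 5) {
  stopifnot(inherits(rec, "seiz_recording"), inherits(seg, "seiz_segment"))
  sr <- rec$sample_rate_hz
  rec_start <- rec$start_offset_s
  rec_end <- rec_start + recording_duration(rec)
  if (seg$start_s < rec_start - 1e-6 || seg$end_s > rec_end + 1e-6)
    stop("segment [", seg$start_s, ", ", seg$end_s,
         "] does not lie within recording [", rec_start, ", ", rec_end, "]")
  wlen <- as.integer(round(window_s * sr))
  i0 <- as.integer(round((seg$start_s - rec_start) * sr))
  total <- as.integer(floor((seg$end_s - seg$start_s) * sr))
  n_win <- total %/% wlen
  nch <- nrow(rec$signal)
  if (n_win == 0) {
    warning("segment shorter than one window (", seg$end_s - seg$start_s,
            " s < ", window_s, " s); empty window set")
    return(window_set(array(0, dim = c(0, nch, wlen)), integer(0),
                      character(0), integer(0), sr, window_s))
  }
  w <- array(0, dim = c(n_win, nch, wlen))
  for (k in seq_len(n_win)) {
    a <- i0 + (k - 1) * wlen
    w[k, , ] <- rec$signal[, (a + 1):(a + wlen), drop = FALSE]
  }
  window_set(w,
             labels = rep(if (seg$label == "preictal") 1L else 0L, n_win),
             patient_ids = rep(seg$patient_id, n_win),
             seizure_indices = rep(seg$source_seizure_index, n_win),
             sample_rate_hz = sr, window_s = window_s)
}

#' Construct a window set
#'
#' The unit of classification: fixed-shape windows with binary labels
#' (1 = preictal, 0 = interictal) and per-window provenance (patient and
#' anchor seizure) used by the leakage audits.
#'
#' @param windows n x channels x samples array.
#' @param labels integer vector in \{0, 1\}, length n.
#' @param patient_ids,seizure_indices per-window provenance, length n.
#' @param sample_rate_hz sampling rate of the windows.
#' @param window_s window length in seconds.
#' @param standardized_with provenance of the statistics the windows were
#'   standardized with, or NA if raw.
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, labels, patient_ids, seizure_indices,
                       sample_rate_hz, window_s,
                       standardized_with = NA_character_) {
  stopifnot(length(dim(windows)) == 3)
  n <- dim(windows)[1]
  stopifnot(length(labels) == n, length(patient_ids) == n,
            length(seizure_indices) == n, all(labels %in% c(0L, 1L)))
  if (abs(dim(windows)[3] - window_s * sample_rate_hz) > 1e-6)
    stop("window sample count (", dim(windows)[3], ") must equal window_s * ",
         "sample_rate_hz (", window_s * sample_rate_hz, ")")
  structure(list(windows = windows, labels = as.integer(labels),
                 patient_ids = as.character(patient_ids),
                 seizure_indices = as.integer(seizure_indices),
                 sample_rate_hz = sample_rate_hz, window_s = window_s,
                 standardized_with = standardized_with),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows x %d ch x %d samples (%g s @ %g Hz); %d preictal / %d interictal%s\n",
              d[1], d[2], d[3], x$window_s, x$sample_rate_hz,
              sum(x$labels == 1), sum(x$labels == 0),
              if (is.na(x$standardized_with)) ""
              else paste0("; standardized [", x$standardized_with, "]")))
  invisible(x)
}

#' Concatenate window sets
#' @param ... `window_set` objects with identical window shape and rate.
#' @return A single `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) sets <- sets[[1]]
  sets <- Filter(function(s) dim(s$windows)[1] > 0, sets)
  stopifnot(length(sets) >= 1)
  d <- dim(sets[[1]]$windows)[-1]
  for (s in sets) stopifnot(all(dim(s$windows)[-1] == d),
                            s$sample_rate_hz == sets[[1]]$sample_rate_hz)
  n <- sum(vapply(sets, function(s) dim(s$windows)[1], 0L))
  w <- array(0, dim = c(n, d))
  at <- 0
  for (s in sets) {
    k <- dim(s$windows)[1]
    if (k) w[(at + 1):(at + k), , ] <- s$windows
    at <- at + k
  }
  window_set(w, unlist(lapply(sets, `[[`, "labels")),
             unlist(lapply(sets, `[[`, "patient_ids")),
             unlist(lapply(sets, `[[`, "seizure_indices")),
             sets[[1]]$sample_rate_hz, sets[[1]]$window_s,
             standardized_with = sets[[1]]$standardized_with)
}

#' Subset a window set
#' @param ws a `window_set`.
#' @param idx integer or logical index over windows.
#' @return A `window_set` with the selected windows.
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$windows[idx, , , drop = FALSE], ws$labels[idx],
             ws$patient_ids[idx], ws$seizure_indices[idx],
             ws$sample_rate_hz, ws$window_s, ws$standardized_with)
}

# ---- standardization ------------------------------------------------------

#' Per-channel mean/std statistics
#'
#' Computed over all time points of a window set or recording. Standard
#' deviations are floored at `std_floor` so dead channels cannot produce
#' infinities downstream.
#'
#' @param source a `window_set` or `seiz_recording`.
#' @param provenance tag recording which data produced the statistics
#'   ("train-split", "per-patient", "pooled-train", "calibration", ...).
#' @param std_floor lower bound on the per-channel std, in microvolts.
#' @return An object of class `channel_stats` with fields `means`, `stds`,
#'   `provenance`.
#' @export
compute_channel_stats <- function(source, provenance = "train-split",
                                  std_floor = 1e-6) {
  if (inherits(source, "seiz_recording")) {
    m <- source$signal
    if (ncol(m) == 0) stop("cannot compute channel stats of an empty recording")
    means <- rowMeans(m)
    stds <- sqrt(rowMeans((m - means)^2))
  } else if (inherits(source, "window_set")) {
    d <- dim(source$windows)
    if (d[1] == 0) stop("cannot compute channel stats of an empty window set")
    means <- numeric(d[2]); stds <- numeric(d[2])
    for (c in seq_len(d[2])) {
      v <- as.numeric(source$windows[, c, ])
      means[c] <- mean(v)
      stds[c] <- sqrt(mean((v - means[c])^2))
    }
  } else stop("source must be a window_set or seiz_recording")
  structure(list(means = means, stds = pmax(stds, std_floor),
                 provenance = provenance),
            class = "channel_stats")
}

#' Pool per-patient channel statistics
#'
#' Pooled mean is the unweighted mean of per-patient means and pooled std the
#' root-mean-square of per-patient stds, so every training patient carries
#' equal weight regardless of recording length — the same patient-equal
#' philosophy as per-patient standardization. Used to standardize the test
#' patient in leave-one-out runs without touching their data.
#'
#' @param stats_list list of `channel_stats`, one per training patient.
#' @return A `channel_stats` with provenance "pooled-train".
#' @export
pool_channel_stats <- function(stats_list) {
  stopifnot(length(stats_list) >= 1)
  m <- sapply(stats_list, `[[`, "means")
  s <- sapply(stats_list, `[[`, "stds")
  structure(list(means = rowMeans(as.matrix(m)),
                 stds = sqrt(rowMeans(as.matrix(s)^2)),
                 provenance = "pooled-train"),
            class = "channel_stats")
}

#' Standardize a window set
#'
#' Per channel: `(x - mean) / std` with the supplied statistics. Which data
#' may supply the statistics is the protocol's responsibility: random
#' cross-validation uses the training split's stats; leave-one-out uses each
#' training patient's own stats for their data and pooled training stats for
#' the test patient; calibration uses the calibration seizures' stats for the
#' whole target-patient signal. Double standardization (which would silently
#' re-center) is refused via the provenance flag.
#'
#' @param ws a `window_set`.
#' @param stats a `channel_stats` with matching channel count.
#' @return The standardized `window_set`.
#' @export
standardize <- function(ws, stats) {
  stopifnot(inherits(ws, "window_set"), inherits(stats, "channel_stats"))
  if (!is.na(ws$standardized_with))
    stop("window set is already standardized [", ws$standardized_with,
         "]; refusing to standardize twice")
  d <- dim(ws$windows)
  if (d[2] != length(stats$means))
    stop("channel mismatch: ", d[2], " channels vs ", length(stats$means),
         " statistics")
  for (c in seq_len(d[2]))
    ws$windows[, c, ] <- (ws$windows[, c, ] - stats$means[c]) / stats$stds[c]
  ws$standardized_with <- stats$provenance
  ws
}
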