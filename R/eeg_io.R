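#' Construct an EEG recording
#'
#' A `seiz_recording` is one continuous multichannel trace: a channels x
#' samples matrix of microvolt values, a sample rate, ordered channel names,
#' and the offset (in seconds) of its first sample on the patient's timeline.
#' All recordings of a patient live on a single seconds axis; gaps between
#' recordings are unrecorded time and no segment may span them.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param sample_rate_hz positive sampling rate in Hz.
#' @param channel_names character vector, one name per signal row.
#' @param patient_id opaque patient identifier.
#' @param start_offset_s seconds from the patient timeline origin to the
#'   first sample.
#' @return An object of class `seiz_recording`.
#' @export
recording <- function(signal, sample_rate_hz, channel_names,
                      patient_id = "unknown", start_offset_s = 0) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be numeric")
  if (length(channel_names) != nrow(signal))
    stop("signal has ", nrow(signal), " rows but ", length(channel_names),
         " channel names were given")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0)
    stop("sample_rate_hz must be a single positive number")
  if (ncol(signal) < 1) stop("recording must contain at least one sample")
  structure(list(
    patient_id = as.character(patient_id),
    channel_names = as.character(channel_names),
    sample_rate_hz = as.numeric(sample_rate_hz),
    signal = signal,
    start_offset_s = as.numeric(start_offset_s)
  ), class = "seiz_recording")
}

#' @export
print.seiz_recording <- function(x, ...) {
  cat(sprintf("<seiz_recording> patient %s: %d ch x %d samples @ %g Hz (t0 = %g s)\n",
              x$patient_id, nrow(x$signal), ncol(x$signal),
              x$sample_rate_hz, x$start_offset_s))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `seiz_recording`.
#' @return length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$sample_rate_hz

#' Construct a seizure event
#'
#' Onset and offset are seconds on the patient timeline; the interval is the
#' ictal span.
#'
#' @param onset_s,offset_s seizure start and end, seconds; `offset_s` must
#'   exceed `onset_s` and `onset_s` must be non-negative.
#' @return An object of class `seiz_event`.
#' @export
seizure_event <- function(onset_s, offset_s) {
  if (!is.finite(onset_s) || !is.finite(offset_s))
    stop("seizure onset/offset must be finite")
  if (onset_s < 0) stop("seizure onset must be >= 0, got ", onset_s)
  if (offset_s <= onset_s)
    stop("seizure offset (", offset_s, ") must exceed onset (", onset_s, ")")
  structure(list(onset_s = as.numeric(onset_s), offset_s = as.numeric(offset_s)),
            class = "seiz_event")
}

#' Assemble a patient record
#'
#' Validates that recordings are non-overlapping and time-ordered, sorts
#' seizures by onset, and rejects any seizure lying outside recorded time.
#'
#' @param patient_id identifier.
#' @param recordings list of `seiz_recording` for this patient.
#' @param seizures list of `seiz_event` on the patient timeline.
#' @param gender optional tag ("m", "f" or NA).
#' @return An object of class `seiz_patient`.
#' @export
patient_record <- function(patient_id, recordings, seizures = list(),
                           gender = NA_character_) {
  stopifnot(length(recordings) >= 1)
  for (r in recordings) {
    if (!inherits(r, "seiz_recording")) stop("recordings must be seiz_recording")
    r$patient_id <- patient_id
  }
  starts <- vapply(recordings, function(r) r$start_offset_s, 0)
  ends <- starts + vapply(recordings, recording_duration, 0)
  o <- order(starts)
  recordings <- recordings[o]; starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)] - 1e-9))
    stop("recordings of patient ", patient_id, " overlap in time")
  if (length(seizures)) {
    seizures <- seizures[order(vapply(seizures, `[[`, 0, "onset_s"))]
    for (s in seizures) {
      inside <- any(s$onset_s >= starts - 1e-9 & s$offset_s <= ends + 1e-9)
      if (!inside)
        stop("seizure [", s$onset_s, ", ", s$offset_s, "] of patient ",
             patient_id, " lies outside recorded time")
    }
  }
  structure(list(
    patient_id = as.character(patient_id),
    recordings = recordings,
    seizures = seizures,
    gender = gender,
    eligible_seizures = integer(0)
  ), class = "seiz_patient")
}

#' @export
print.seiz_patient <- function(x, ...) {
  cat(sprintf("<seiz_patient> %s: %d recording(s), %d seizure(s)\n",
              x$patient_id, length(x$recordings), length(x$seizures)))
  invisible(x)
}

#' Recorded time spans of a patient
#' @param patient a `seiz_patient`.
#' @return data.frame with columns `start_s`, `end_s`, one row per recording.
#' @export
recorded_spans <- function(patient) {
  starts <- vapply(patient$recordings, function(r) r$start_offset_s, 0)
  ends <- starts + vapply(patient$recordings, recording_duration, 0)
  data.frame(start_s = starts, end_s = ends)
}

# ---- EDF ------------------------------------------------------------------

#' Read an EDF file
#'
#' Minimal reader for the European Data Format: 256-byte fixed header,
#' per-signal ASCII subheaders, then little-endian int16 data records scaled
#' to physical units. Signals are converted to microvolts (physical
#' dimensions "uV" and "mV" are understood; anything else is taken verbatim
#' with a warning).
#'
#' @param path path to an EDF file.
#' @param patient_id patient identifier to attach (default: from the file's
#'   local patient field, falling back to the file name).
#' @param start_offset_s patient-timeline offset of the first sample.
#' @return A `seiz_recording`.
#' @export
read_edf <- function(path, patient_id = NULL, start_offset_s = 0) {
  if (!file.exists(path)) stop("EDF file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256)
    stop("not a valid EDF file (truncated header): ", path)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  pat_field <- fld(hdr, 9, 80)
  n_records <- suppressWarnings(as.integer(fld(hdr, 237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(hdr, 245, 8)))
  ns <- suppressWarnings(as.integer(fld(hdr, 253, 4)))
  if (is.na(ns) || is.na(n_records) || is.na(rec_dur))
    stop("not a valid EDF file (malformed header): ", path)
  if (ns < 1) stop("EDF file declares zero signals: ", path)
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256 * ns)
    stop("not a valid EDF file (truncated signal header): ", path)
  grab <- function(width, at) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, at + (i - 1) * width + 1, at + i * width)), "")
  }
  labels <- grab(16, 0)
  phys_dim <- grab(8, ns * (16 + 80))
  phys_min <- as.numeric(grab(8, ns * (16 + 80 + 8)))
  phys_max <- as.numeric(grab(8, ns * (16 + 80 + 16)))
  dig_min <- as.numeric(grab(8, ns * (16 + 80 + 24)))
  dig_max <- as.numeric(grab(8, ns * (16 + 80 + 32)))
  spr <- as.integer(grab(8, ns * (16 + 80 + 40 + 80)))
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)))
    stop("not a valid EDF file (malformed signal header): ", path)
  rates <- spr / rec_dur
  if (length(unique(rates)) != 1)
    stop("unsupported EDF layout: signals have differing sample rates in ", path)
  raw_all <- readBin(con, "integer", n = n_records * sum(spr), size = 2,
                     signed = TRUE, endian = "little")
  if (length(raw_all) < n_records * sum(spr))
    stop("not a valid EDF file (truncated data): ", path)
  sig <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  idx <- 0
  per_rec <- sum(spr)
  for (r in seq_len(n_records)) {
    rec_block <- raw_all[(idx + 1):(idx + per_rec)]
    pos <- 0
    for (i in seq_len(ns)) {
      sig[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        rec_block[(pos + 1):(pos + spr[i])]
      pos <- pos + spr[i]
    }
    idx <- idx + per_rec
  }
  # digital -> physical
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in seq_len(ns))
    sig[i, ] <- (sig[i, ] - dig_min[i]) * gain[i] + phys_min[i]
  # unit conversion to microvolts
  for (i in seq_len(ns)) {
    u <- tolower(phys_dim[i])
    if (u %in% c("mv")) sig[i, ] <- sig[i, ] * 1000
    else if (u %in% c("v")) sig[i, ] <- sig[i, ] * 1e6
    else if (!u %in% c("uv", "µv", ""))
      warning("unknown physical dimension '", phys_dim[i], "' in ", path,
              "; values taken as microvolts")
  }
  if (is.null(patient_id))
    patient_id <- if (nzchar(pat_field)) strsplit(pat_field, " ")[[1]][1]
                  else basename(path)
  recording(sig, rates[1], labels, patient_id, start_offset_s)
}

#' Write a recording to an EDF file
#'
#' Companion writer used by the synthetic cohort exporter and by tests.
#' Values are quantized to 16 bits over the per-channel physical range, in
#' 1-second data records; a trailing sub-second remainder is dropped with a
#' warning.
#'
#' @param rec a `seiz_recording` (microvolt values).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "seiz_recording"))
  sr <- rec$sample_rate_hz
  if (abs(sr - round(sr)) > 1e-9) stop("EDF writer requires an integer sample rate")
  sr <- as.integer(round(sr))
  ns <- nrow(rec$signal)
  n_rec <- ncol(rec$signal) %/% sr
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  if (n_rec * sr != ncol(rec$signal))
    warning("dropping ", ncol(rec$signal) - n_rec * sr,
            " trailing samples (EDF records are 1 s)")
  sig <- rec$signal[, seq_len(n_rec * sr), drop = FALSE]
  pmin_ <- apply(sig, 1, min); pmax_ <- apply(sig, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  pad <- function(x, w) {
    s <- formatC(x, width = w, flag = "-")
    substr(s, 1, w)
  }
  num <- function(x, w) pad(formatC(x, format = "g", digits = 7), w)
  hdr <- paste0(
    pad("0", 8), pad(rec$patient_id, 80), pad("seizcal", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(as.character(256 * (1 + ns)), 8), pad("", 44),
    pad(as.character(n_rec), 8), pad("1", 8), pad(as.character(ns), 4))
  shdr <- paste0(
    paste(vapply(rec$channel_names, pad, "", 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin_, num, "", 8), collapse = ""),
    paste(vapply(pmax_, num, "", 8), collapse = ""),
    paste(rep(pad(as.character(dmin), 8), ns), collapse = ""),
    paste(rep(pad(as.character(dmax), 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(as.character(sr), 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  # re-read physical extremes exactly as the reader will parse them, so the
  # quantization grid is anchored to the header values, not the doubles
  pmin_h <- as.numeric(vapply(pmin_, num, "", 8))
  pmax_h <- as.numeric(vapply(pmax_, num, "", 8))
  gain <- (dmax - dmin) / (pmax_h - pmin_h)
  dig <- matrix(0L, ns, ncol(sig))
  for (i in seq_len(ns)) {
    d <- round((sig[i, ] - pmin_h[i]) * gain[i]) + dmin
    dig[i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(hdr, shdr), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    block <- t(dig[, ((r - 1) * sr + 1):(r * sr), drop = FALSE])
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

# ---- channel selection ----------------------------------------------------

#' Restrict a recording to a common channel set
#'
#' Returns the recording with exactly the requested channels in the requested
#' order. Idempotent: reapplying the same request is a no-op. The common
#' channel list is a configuration input (which channels are shared across a
#' cohort depends on the montage of each dataset).
#'
#' @param rec a `seiz_recording`.
#' @param channels character vector of channel names, in the desired order.
#' @return A `seiz_recording` with the requested channels.
#' @export
select_common_channels <- function(rec, channels) {
  stopifnot(inherits(rec, "seiz_recording"))
  idx <- match(channels, rec$channel_names)
  if (anyNA(idx))
    stop("recording ", rec$patient_id, " is missing channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  rec$signal <- rec$signal[idx, , drop = FALSE]
  rec$channel_names <- rec$channel_names[idx]
  rec
}

# ---- annotations ----------------------------------------------------------

#' Parse seizure annotations
#'
#' Two dialects are understood. The summary dialect used by public scalp-EEG
#' archives is a plain-text document of file blocks:
#'
#' ```
#' File Name: chb01_03.edf
#' Number of Seizures in File: 1
#' Seizure 1 Start Time: 2996 seconds
#' Seizure 1 End Time: 3036 seconds
#' ```
#'
#' The CSV sidecar dialect has a header `file,onset_s,offset_s` with in-file
#' seconds. In both cases events are mapped to the patient timeline by adding
#' the per-file start offsets and returned sorted by onset.
#'
#' @param text character scalar (whole document) or vector of lines.
#' @param file_offsets named numeric vector: patient-timeline offset (s) of
#'   each file's first sample.
#' @return list of `seiz_event`, sorted by onset.
#' @export
parse_seizure_annotations <- function(text, file_offsets) {
  lines <- if (length(text) == 1 && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^file\\s*,\\s*onset_s\\s*,\\s*offset_s", lines[1],
                             ignore.case = TRUE)) {
    df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
    events <- .annotation_rows(df$file, df$onset_s, df$offset_s,
                               seq_len(nrow(df)) + 1, file_offsets)
  } else {
    cur_file <- NA_character_
    files <- character(); onsets <- numeric(); offsets <- numeric()
    lineno <- integer()
    pending_start <- NULL; pending_line <- NA_integer_
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (grepl("^File Name\\s*:", ln, ignore.case = TRUE)) {
        cur_file <- trimws(sub("^File Name\\s*:", "", ln, ignore.case = TRUE))
        pending_start <- NULL
      } else if (grepl("^Seizure.*Start Time\\s*:", ln, ignore.case = TRUE)) {
        pending_start <- as.numeric(sub(".*:\\s*([0-9.]+).*", "\\1", ln))
        pending_line <- i
      } else if (grepl("^Seizure.*End Time\\s*:", ln, ignore.case = TRUE)) {
        v <- as.numeric(sub(".*:\\s*([0-9.]+).*", "\\1", ln))
        if (is.null(pending_start))
          stop("line ", i, ": seizure end without a preceding start")
        files <- c(files, cur_file)
        onsets <- c(onsets, pending_start)
        offsets <- c(offsets, v)
        lineno <- c(lineno, i)
        pending_start <- NULL
      }
    }
    events <- .annotation_rows(files, onsets, offsets, lineno, file_offsets)
  }
  events[order(vapply(events, `[[`, 0, "onset_s"))]
}

.annotation_rows <- function(files, onsets, offsets, lineno, file_offsets) {
  out <- vector("list", length(files))
  for (k in seq_along(files)) {
    if (is.na(files[k]))
      stop("line ", lineno[k], ": seizure declared before any File Name")
    if (!(files[k] %in% names(file_offsets)))
      stop("annotation references file '", files[k],
           "' which is absent from the cohort")
    if (is.na(onsets[k]) || is.na(offsets[k]) || offsets[k] <= onsets[k])
      stop("line ", lineno[k], ": seizure end (", offsets[k],
           ") must exceed start (", onsets[k], ")")
    base <- file_offsets[[files[k]]]
    out[[k]] <- seizure_event(base + onsets[k], base + offsets[k])
  }
  out
}
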