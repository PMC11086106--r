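#' Labeling parameters
#'
#' Defaults follow the standard forecasting setup: a 15-minute preictal
#' horizon ending at seizure onset, a 4-hour buffer between the interictal
#' and preictal states, up to 60 minutes of interictal data, and interictal
#' undersampling to 15 contiguous minutes so the two classes are balanced.
#'
#' @param preictal_min preictal horizon, minutes.
#' @param gap_hours buffer between interictal end and preictal start, hours.
#' @param interictal_max_min maximum interictal length, minutes.
#' @param undersample_min interictal length kept after undersampling, minutes.
#' @return An object of class `labeling_params`.
#' @export
labeling_params <- function(preictal_min = 15, gap_hours = 4,
                            interictal_max_min = 60, undersample_min = 15) {
  stopifnot(preictal_min > 0, gap_hours > 0, interictal_max_min > 0,
            undersample_min > 0, interictal_max_min >= undersample_min)
  structure(list(preictal_min = preictal_min, gap_hours = gap_hours,
                 interictal_max_min = interictal_max_min,
                 undersample_min = undersample_min),
            class = "labeling_params")
}

#' A labeled segment
#'
#' @param patient_id patient identifier.
#' @param label "preictal" or "interictal".
#' @param start_s,end_s patient-timeline seconds, `end_s > start_s`.
#' @param source_seizure_index index of the seizure this segment is anchored
#'   to (1-based within the patient's seizure list).
#' @return An object of class `seiz_segment`.
#' @export
segment <- function(patient_id, label, start_s, end_s, source_seizure_index) {
  label <- match.arg(label, c("preictal", "interictal"))
  if (end_s <= start_s)
    stop("segment end (", end_s, ") must exceed start (", start_s, ")")
  structure(list(patient_id = patient_id, label = label,
                 start_s = start_s, end_s = end_s,
                 source_seizure_index = as.integer(source_seizure_index)),
            class = "seiz_segment")
}

#' @export
print.seiz_segment <- function(x, ...) {
  cat(sprintf("<seiz_segment> %s %s [%g, %g] s (seizure %d)\n", x$patient_id,
              x$label, x$start_s, x$end_s, x$source_seizure_index))
  invisible(x)
}

# Length (s) of contiguous recorded, seizure-free time ending at `t`.
# A recording gap or any ictal span cuts the lookback.
.clean_lookback <- function(patient, t) {
  spans <- recorded_spans(patient)
  row <- which(spans$start_s <= t + 1e-9 & spans$end_s >= t - 1e-9)
  if (!length(row)) return(0)
  lo <- spans$start_s[max(row)]
  for (s in patient$seizures) {
    if (s$offset_s <= t + 1e-9 && s$offset_s > lo) lo <- s$offset_s
  }
  max(t - lo, 0)
}

#' Find seizures eligible for labeling
#'
#' A seizure is eligible when strictly more than `gap_hours + preictal_min`
#' of contiguous recorded, seizure-free time precedes its onset — enough room
#' for both the preictal window and the separating buffer, uncontaminated by
#' recording gaps or earlier ictal activity. (A plain "more than four hours
#' before onset" rule would leave zero interictal time once the preictal
#' window is carved out.)
#'
#' @param patient a `seiz_patient`.
#' @param params a `labeling_params`.
#' @return Integer vector of eligible seizure indices (possibly empty).
#' @seealso [patient_eligible_for_leaveout()]
#' @export
find_eligible_seizures <- function(patient, params = labeling_params()) {
  need <- params$gap_hours * 3600 + params$preictal_min * 60
  idx <- integer(0)
  for (i in seq_along(patient$seizures)) {
    s <- patient$seizures[[i]]
    if (.clean_lookback(patient, s$onset_s) > need) idx <- c(idx, i)
  }
  idx
}

#' Is a patient eligible for leave-out validation and calibration?
#'
#' Patients with a single seizure contribute to training only; at least two
#' seizures are required to hold data out for testing or calibration.
#'
#' @param patient a `seiz_patient`.
#' @return TRUE if the patient has at least two seizures.
#' @export
patient_eligible_for_leaveout <- function(patient) {
  length(patient$seizures) >= 2
}

#' Label one seizure's preictal/interictal pair
#'
#' The preictal segment is the `preictal_min` minutes ending exactly at
#' onset. The interictal segment ends `gap_hours` before the preictal start
#' and extends backwards up to `interictal_max_min` minutes, truncated at
#' the start of contiguous clean time (recording start, gap boundary, or the
#' previous seizure's offset — baseline activity must come from the same
#' uninterrupted stretch).
#'
#' @param patient a `seiz_patient`.
#' @param seizure_index index into `patient$seizures`; must be eligible.
#' @param params a `labeling_params`.
#' @return list with elements `preictal` and `interictal`, both `seiz_segment`.
#' @export
label_seizure <- function(patient, seizure_index, params = labeling_params()) {
  s <- patient$seizures[[seizure_index]]
  onset <- s$onset_s
  pre_start <- onset - params$preictal_min * 60
  inter_end <- pre_start - params$gap_hours * 3600
  avail <- .clean_lookback(patient, onset) -
    (params$preictal_min * 60 + params$gap_hours * 3600)
  inter_len <- min(params$interictal_max_min * 60, avail)
  if (inter_len <= 0)
    stop("seizure ", seizure_index, " of patient ", patient$patient_id,
         ": no interictal time available before the separating buffer")
  list(
    preictal = segment(patient$patient_id, "preictal", pre_start, onset,
                       seizure_index),
    interictal = segment(patient$patient_id, "interictal",
                         inter_end - inter_len, inter_end, seizure_index)
  )
}

#' Undersample an interictal segment
#'
#' Draws a contiguous sub-segment of `undersample_min` minutes with a start
#' uniform over the feasible range, balancing the interictal class against
#' the fixed-length preictal class. Segments already at or below the target
#' length are returned unchanged with a warning.
#'
#' @param seg an interictal `seiz_segment`.
#' @param params a `labeling_params`.
#' @param seed integer seed; the same seed reproduces the same draw.
#' @return A `seiz_segment` of at most `undersample_min` minutes.
#' @export
undersample_interictal <- function(seg, params = labeling_params(), seed = 1) {
  stopifnot(inherits(seg, "seiz_segment"))
  if (seg$label != "interictal")
    stop("undersample_interictal expects an interictal segment, got ", seg$label)
  target <- params$undersample_min * 60
  len <- seg$end_s - seg$start_s
  if (len <= target) {
    if (len < target)
      warning("interictal segment (", round(len / 60, 2),
              " min) shorter than undersample target; returned unchanged")
    return(seg)
  }
  start <- withr::with_seed(seed,
                            stats::runif(1, 0, len - target)) + seg$start_s
  segment(seg$patient_id, "interictal", start, start + target,
          seg$source_seizure_index)
}

#' Label every eligible seizure of a cohort
#'
#' Convenience wrapper: applies [find_eligible_seizures()], [label_seizure()]
#' and [undersample_interictal()] across a cohort.
#'
#' @param cohort list of `seiz_patient`.
#' @param params a `labeling_params`.
#' @param seed base seed for undersampling draws.
#' @return data.frame with one row per labeled segment: `patient_id`, `label`,
#'   `start_s`, `end_s`, `seizure_index`.
#' @export
label_cohort <- function(cohort, params = labeling_params(), seed = 1) {
  rows <- list()
  for (p in cohort) {
    for (i in find_eligible_seizures(p, params)) {
      lab <- label_seizure(p, i, params)
      inter <- undersample_interictal(lab$interictal, params,
                                      seed = seed + 7919L * i +
                                        .patient_hash(p$patient_id))
      for (sg in list(lab$preictal, inter))
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = sg$patient_id, label = sg$label,
          start_s = sg$start_s, end_s = sg$end_s,
          seizure_index = sg$source_seizure_index)
    }
  }
  if (!length(rows))
    return(data.frame(patient_id = character(), label = character(),
                      start_s = numeric(), end_s = numeric(),
                      seizure_index = integer()))
  do.call(rbind, rows)
}

# small stable hash so per-patient undersampling draws decorrelate
.patient_hash <- function(id) {
  sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 10000L
}
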