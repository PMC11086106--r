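#' Prepare a cohort for experiments: preprocess, label, window
#'
#' Runs the fixed pipeline (filter at the native rate, decimate, cut labeled
#' segments, window) for every patient, returning raw (unstandardized)
#' windows with full provenance. Standardization is deliberately left to the
#' individual validation protocols, which differ in which data may supply
#' the statistics. For seizures that fail the full eligibility rule but
#' still have one preictal horizon of contiguous clean lookback, the
#' preictal windows are kept (flagged `paired = FALSE`): they may serve as
#' the second calibration seizure, with the first seizure's interictal
#' standing in as their matched background.
#'
#' @param cohort list of `seiz_patient`.
#' @param params a `labeling_params`.
#' @param window_s window length, seconds.
#' @param target_rate_hz post-decimation rate.
#' @param seed base seed for interictal undersampling.
#' @return An object of class `prepared_cohort`: per patient, a raw
#'   `window_set` and a seizure table (`seizure_index`, `paired`).
#' @export
prepare_cohort_windows <- function(cohort, params = labeling_params(),
                                   window_s = 5, target_rate_hz = 128,
                                   seed = 1) {
  patients <- list()
  for (p in cohort) {
    eligible <- find_eligible_seizures(p, params)
    proc <- lapply(p$recordings, preprocess_recording,
                   target_rate_hz = target_rate_hz)
    spans <- recorded_spans(p)
    cut <- function(seg) {
      k <- which(spans$start_s <= seg$start_s + 1e-6 &
                   spans$end_s >= seg$end_s - 1e-6)[1]
      if (is.na(k)) stop("segment does not fall inside a single recording")
      segment_to_windows(proc[[k]], seg, window_s)
    }
    sets <- list()
    seiz_rows <- list()
    for (i in eligible) {
      lab <- label_seizure(p, i, params)
      inter <- undersample_interictal(lab$interictal, params,
                                      seed = seed + 7919L * i +
                                        .patient_hash(p$patient_id))
      sets[[length(sets) + 1]] <- cut(lab$preictal)
      sets[[length(sets) + 1]] <- cut(inter)
      seiz_rows[[length(seiz_rows) + 1]] <-
        data.frame(seizure_index = i, paired = TRUE)
    }
    # preictal-only seizures (candidate second calibration events)
    need_pre <- params$preictal_min * 60
    for (i in setdiff(seq_along(p$seizures), eligible)) {
      s <- p$seizures[[i]]
      if (.clean_lookback(p, s$onset_s) >= need_pre + window_s) {
        seg <- segment(p$patient_id, "preictal", s$onset_s - need_pre,
                       s$onset_s, i)
        sets[[length(sets) + 1]] <- cut(seg)
        seiz_rows[[length(seiz_rows) + 1]] <-
          data.frame(seizure_index = i, paired = FALSE)
      }
    }
    if (!length(sets)) next
    patients[[p$patient_id]] <- list(
      windows = bind_window_sets(sets),
      seizures = do.call(rbind, seiz_rows),
      n_seizures = length(p$seizures))
  }
  structure(list(patients = patients, window_s = window_s,
                 sample_rate_hz = target_rate_hz, params = params),
            class = "prepared_cohort")
}

#' @export
print.prepared_cohort <- function(x, ...) {
  cat(sprintf("<prepared_cohort> %d patient(s), %d windows total\n",
              length(x$patients),
              sum(vapply(x$patients,
                         function(p) dim(p$windows$windows)[1], 0L))))
  invisible(x)
}

# windows of the paired (fully labeled) seizures only
.paired_windows <- function(entry) {
  keep <- entry$windows$seizure_indices %in%
    entry$seizures$seizure_index[entry$seizures$paired]
  subset_windows(entry$windows, keep)
}

# ---- classifier factories -------------------------------------------------

#' Classifier factory for the convolutional model
#'
#' Adapts the CNN to the common interface the experiment runners consume:
#' `fit(ws, seed, condition)`, `predict(model, ws)`,
#' `finetune(model, cal_ws, seed)`. The epoch budget may differ by
#' validation condition (the pooled RCV task typically needs more epochs
#' than the LOO transfer baseline at a fixed wall-clock budget).
#'
#' @param spec a `cnn_spec`.
#' @param config a `train_config`.
#' @param epochs_by_condition optional named vector, e.g.
#'   `c(RCV = 4, LOO = 2)`, overriding `config$max_epochs` per condition.
#' @return A classifier factory list.
#' @export
cnn_classifier <- function(spec = cnn_spec(), config = train_config(),
                           epochs_by_condition = NULL) {
  list(
    name = "cnn",
    fit = function(ws, seed, condition = "RCV") {
      d <- dim(ws$windows)
      cfg <- config; cfg$seed <- as.integer(seed)
      if (!is.null(epochs_by_condition) &&
          condition %in% names(epochs_by_condition))
        cfg$max_epochs <- as.integer(epochs_by_condition[[condition]])
      m <- build_model(d[2], d[3], spec, seed = seed)
      train_model(m, ws, cfg)
    },
    predict = function(model, ws) predict_proba(model, ws),
    finetune = function(model, cal_ws, seed) {
      cfg <- config; cfg$seed <- as.integer(seed)
      fine_tune(model, cal_ws, cfg)
    })
}

#' Classifier factory for the 53-feature gradient-boosted baseline
#'
#' @param nrounds,extra_rounds boosting rounds for training / calibration.
#' @param max_depth,eta booster parameters.
#' @return A classifier factory list.
#' @export
baseline_classifier <- function(nrounds = 60, extra_rounds = 20,
                                max_depth = 3, eta = 0.3) {
  feats <- function(ws) extract_feature_table(ws)
  list(
    name = "xgb",
    fit = function(ws, seed, condition = "RCV") {
      tb <- feats(ws)
      train_baseline(tb, tb$label, nrounds = nrounds, max_depth = max_depth,
                     eta = eta, seed = seed)
    },
    predict = function(model, ws) predict(model, feats(ws)),
    finetune = function(model, cal_ws, seed) {
      tb <- feats(cal_ws)
      calibrate_baseline(model, tb, tb$label, extra_rounds = extra_rounds,
                         seed = seed)
    })
}

# ---- per-patient metric aggregation --------------------------------------

.per_patient_metrics <- function(probs, labels, pids) {
  out <- list()
  for (pid in unique(pids)) {
    sel <- pids == pid
    out[[pid]] <- suppressWarnings(compute_metrics(probs[sel], labels[sel]))
  }
  out
}

# ---- RCV ------------------------------------------------------------------

#' Randomized k-fold cross-validation over pooled windows
#'
#' Windows from all patients are pooled and split into k random folds at the
#' window level — deliberately not patient-stratified, since the point of
#' this condition is that every patient contributes to every training set,
#' which inflates scores relative to patient-independent validation. Per
#' fold, channel statistics come from the training split only; per-patient
#' metrics pool each patient's test windows across folds.
#'
#' @param prepared a `prepared_cohort`.
#' @param classifier a classifier factory ([cnn_classifier()] /
#'   [baseline_classifier()]).
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling fold assignment and training.
#' @return list with `per_patient` (named list of `eval_metrics`),
#'   `summary`, and `condition = "RCV"`.
#' @export
run_rcv <- function(prepared, classifier, k = 5, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  all_ws <- bind_window_sets(lapply(prepared$patients, .paired_windows))
  n <- dim(all_ws$windows)[1]
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  probs <- numeric(n)
  for (f in seq_len(k)) {
    tr <- subset_windows(all_ws, fold != f)
    te <- subset_windows(all_ws, fold == f)
    st <- compute_channel_stats(tr, provenance = "train-split")
    m <- classifier$fit(standardize(tr, st), seed = seed + f,
                        condition = "RCV")
    probs[fold == f] <- classifier$predict(m, standardize(te, st))
  }
  pp <- .per_patient_metrics(probs, all_ws$labels, all_ws$patient_ids)
  list(condition = "RCV", per_patient = pp,
       summary = .metric_summary(pp))
}

.metric_summary <- function(pp) {
  m <- sapply(pp, function(e) c(acc = e$acc, sen = e$sen, spe = e$spe,
                                auc = e$auc))
  list(mean = rowMeans(m, na.rm = TRUE),
       std = apply(m, 1, stats::sd, na.rm = TRUE))
}

# ---- LOO ------------------------------------------------------------------

#' Leave-one-patient-out validation
#'
#' The target patient's windows are entirely excluded from training and from
#' every statistic: each training patient is standardized with their own
#' channel statistics, while the target is standardized with the pooled
#' (patient-equal) training statistics. Patients with a single labeled
#' seizure still contribute to training; only patients with at least two
#' seizures are valid targets.
#'
#' @param prepared a `prepared_cohort`.
#' @param classifier a classifier factory.
#' @param target_patient patient id to leave out.
#' @param seed integer training seed.
#' @return list with `metrics` (an `eval_metrics` over all target windows),
#'   `model` (the trained patient-independent checkpoint), `probs`,
#'   `provenance` (patients/statistics used, for the leakage audit).
#' @export
run_loo <- function(prepared, classifier, target_patient, seed = 1) {
  entry <- prepared$patients[[target_patient]]
  if (is.null(entry)) stop("unknown patient: ", target_patient)
  if (entry$n_seizures < 2)
    stop("patient ", target_patient, " has a single seizure and is only ",
         "eligible as training data, not as a leave-out target")
  train_ids <- setdiff(names(prepared$patients), target_patient)
  tr_sets <- list(); tr_stats <- list()
  for (pid in train_ids) {
    ws <- .paired_windows(prepared$patients[[pid]])
    st <- compute_channel_stats(ws, provenance = paste0("per-patient:", pid))
    tr_stats[[pid]] <- st
    tr_sets[[pid]] <- standardize(ws, st)
  }
  tr <- bind_window_sets(tr_sets)
  pooled <- pool_channel_stats(tr_stats)
  model <- classifier$fit(tr, seed = seed, condition = "LOO")
  te <- standardize(.paired_windows(entry), pooled)
  probs <- classifier$predict(model, te)
  list(condition = "LOO", target = target_patient,
       metrics = suppressWarnings(compute_metrics(probs, te$labels)),
       model = model, probs = probs,
       provenance = list(train_patients = train_ids,
                         stats_patients = train_ids,
                         cal_seizures = integer(0)))
}

# ---- calibration ----------------------------------------------------------

#' Calibrate the patient-independent model on target-patient seizures
#'
#' Cal1 fine-tunes the leave-one-out checkpoint on the target's first
#' (chronological) fully labeled seizure; Cal2 adds a second seizure drawn
#' seeded-uniformly from the remainder. If the drawn second seizure lacks
#' its own interictal lookback, the first seizure's interictal windows stand
#' in as its background class, keeping the calibration set balanced. The
#' whole target signal — calibration and test alike — is standardized with
#' statistics computed from the calibration windows only. Evaluation uses
#' the target's remaining fully labeled seizures.
#'
#' @param prepared a `prepared_cohort`.
#' @param classifier a classifier factory.
#' @param target_patient patient id.
#' @param loo_fit result of [run_loo()] for the same target (its `model`
#'   field is never mutated).
#' @param n_cal_seizures 1 (Cal1) or 2 (Cal2).
#' @param seed seed for the second-seizure draw and fine-tuning.
#' @return list with `metrics`, `model`, `cal_seizures`, `provenance`.
#' @export
run_calibration <- function(prepared, classifier, target_patient, loo_fit,
                            n_cal_seizures = 1, seed = 1) {
  stopifnot(n_cal_seizures %in% c(1, 2))
  entry <- prepared$patients[[target_patient]]
  if (is.null(entry)) stop("unknown patient: ", target_patient)
  paired <- entry$seizures$seizure_index[entry$seizures$paired]
  if (length(paired) < n_cal_seizures + 1)
    stop("patient ", target_patient, ": calibration with ", n_cal_seizures,
         " seizure(s) would leave no labeled seizure for testing")
  cal1 <- min(paired)                       # first chronological eligible
  cal <- cal1
  borrow <- FALSE
  if (n_cal_seizures == 2) {
    pool <- setdiff(entry$seizures$seizure_index, cal1)
    # the drawn seizure must leave at least one paired seizure for testing
    pool <- pool[!(pool %in% paired) |
                   vapply(pool, function(i)
                     length(setdiff(paired, c(cal1, i))) >= 1, TRUE)]
    cal2 <- if (length(pool) == 1) pool else
      withr::with_seed(seed, sample(pool, 1))
    borrow <- !(cal2 %in% paired)
    cal <- c(cal1, cal2)
  }
  ws <- entry$windows
  in_cal <- ws$seizure_indices %in% cal
  if (borrow) {
    # second seizure has no interictal: reuse the first seizure's
    extra <- ws$seizure_indices == cal1 & ws$labels == 0L
    in_cal <- in_cal | extra
  }
  cal_raw <- subset_windows(ws, in_cal)
  st <- compute_channel_stats(cal_raw, provenance = "calibration")
  cal_ws <- standardize(cal_raw, st)
  test_idx <- setdiff(entry$seizures$seizure_index[entry$seizures$paired], cal)
  te_raw <- subset_windows(ws, ws$seizure_indices %in% test_idx)
  te <- standardize(te_raw, st)
  model <- classifier$finetune(loo_fit$model, cal_ws, seed = seed)
  probs <- classifier$predict(model, te)
  list(condition = paste0("Cal", n_cal_seizures), target = target_patient,
       metrics = suppressWarnings(compute_metrics(probs, te$labels)),
       model = model, cal_seizures = cal, probs = probs,
       provenance = list(train_patients = loo_fit$provenance$train_patients,
                         stats_patients = "calibration",
                         cal_seizures = cal, test_seizures = test_idx))
}

#' Audit a leave-out or calibration run for leakage
#'
#' Verifies from the recorded provenance that no window of the target
#' patient contributed to training or to standardization statistics beyond
#' the declared calibration seizures.
#'
#' @param run result of [run_loo()] or [run_calibration()].
#' @param target_patient the target id.
#' @return TRUE (invisibly); errors when leakage is detected.
#' @export
audit_leakage <- function(run, target_patient) {
  pv <- run$provenance
  if (target_patient %in% pv$train_patients)
    stop("leakage: target patient present in the training set")
  if (!identical(pv$stats_patients, "calibration") &&
      target_patient %in% pv$stats_patients)
    stop("leakage: target patient contributed to standardization statistics")
  invisible(TRUE)
}

# ---- full suite -----------------------------------------------------------

#' Run the full validation suite on a prepared cohort
#'
#' RCV over all patients, then LOO, Cal1 and Cal2 for every eligible target
#' (at least two labeled seizures, with one left over after calibration).
#' Returns the per-patient condition table, summary statistics,
#' repeated-measures ANOVA and Tukey post hoc results per metric.
#'
#' @param prepared a `prepared_cohort`.
#' @param classifier a classifier factory.
#' @param k RCV folds.
#' @param seed master seed.
#' @param conditions subset of conditions to run.
#' @return An object of class `experiment_suite`: `table` (long data.frame:
#'   patient, condition, metric, value), `wide` (list of patients x
#'   conditions matrices per metric), `anova`, `tukey`, `summary`.
#' @export
run_experiment_suite <- function(prepared, classifier, k = 5, seed = 1,
                                 conditions = c("RCV", "LOO", "Cal1", "Cal2")) {
  rows <- list()
  add <- function(pid, cond, m) {
    for (metric in c("acc", "sen", "spe"))
      rows[[length(rows) + 1]] <<- data.frame(
        patient = pid, condition = cond, metric = toupper(metric),
        value = 100 * m[[metric]])
  }
  if ("RCV" %in% conditions) {
    rcv <- run_rcv(prepared, classifier, k = k, seed = seed)
    for (pid in names(rcv$per_patient)) add(pid, "RCV", rcv$per_patient[[pid]])
  }
  targets <- names(prepared$patients)[vapply(prepared$patients, function(e)
    sum(e$seizures$paired) >= 2 && e$n_seizures >= 2, TRUE)]
  for (ti in seq_along(targets)) {
    pid <- targets[ti]
    loo <- run_loo(prepared, classifier, pid, seed = seed + 100 + ti)
    audit_leakage(loo, pid)
    if ("LOO" %in% conditions) add(pid, "LOO", loo$metrics)
    for (ncal in 1:2) {
      cond <- paste0("Cal", ncal)
      if (!cond %in% conditions) next
      n_paired <- sum(prepared$patients[[pid]]$seizures$paired)
      if (n_paired < ncal + 1) next
      cal <- run_calibration(prepared, classifier, pid, loo,
                             n_cal_seizures = ncal, seed = seed + 200 + ti)
      audit_leakage(cal, pid)
      add(pid, cond, cal$metrics)
    }
  }
  table <- do.call(rbind, rows)
  wide <- list()
  for (metric in unique(table$metric)) {
    sub <- table[table$metric == metric, ]
    w <- stats::reshape(sub[, c("patient", "condition", "value")],
                        idvar = "patient", timevar = "condition",
                        direction = "wide")
    rownames(w) <- w$patient
    w$patient <- NULL
    colnames(w) <- sub("^value\\.", "", colnames(w))
    wide[[metric]] <- as.matrix(w)
  }
  anova <- list(); tukey <- list()
  cal_conds <- intersect(c("LOO", "Cal1", "Cal2"), colnames(wide[[1]]))
  for (metric in names(wide)) {
    m <- wide[[metric]][, cal_conds, drop = FALSE]
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) >= 2 && ncol(m) >= 2) {
      anova[[metric]] <- rm_anova(m)
      tukey[[metric]] <- tukey_posthoc(m)
    }
  }
  structure(list(table = table, wide = wide, anova = anova, tukey = tukey,
                 summary = lapply(wide, summarize_conditions)),
            class = "experiment_suite")
}

#' @export
print.experiment_suite <- function(x, ...) {
  cat("<experiment_suite>\n")
  for (metric in names(x$wide)) {
    s <- x$summary[[metric]]
    cat(sprintf("  %s: %s\n", metric,
                paste(sprintf("%s %.2f±%.2f", names(s$mean), s$mean, s$std),
                      collapse = "  ")))
    if (!is.null(x$anova[[metric]]))
      cat(sprintf("    rm-ANOVA F(%d,%d) = %.2f, p = %.3g\n",
                  x$anova[[metric]]$df_condition, x$anova[[metric]]$df_error,
                  x$anova[[metric]]$f_value, x$anova[[metric]]$p_value))
  }
  invisible(x)
}
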