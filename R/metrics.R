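#' Window-classification evaluation metrics
#'
#' Confusion counts at the given threshold, with accuracy, sensitivity
#' (true-positive rate on preictal) and specificity (true-negative rate on
#' interictal):
#' ACC = (tp + tn) / (tp + tn + fn + fp), SEN = tp / (tp + fn),
#' SPE = tn / (tn + fp). The ROC curve is traced by sweeping the threshold
#' over the sorted unique probabilities and the AUC computed by the
#' trapezoidal rule. If a class is absent from `labels`, the corresponding
#' rate (and the AUC) is reported as NA with a warning, never as 0, so that
#' averaging denominators shrink rather than being dragged down.
#'
#' @param probabilities preictal probabilities in \[0, 1\].
#' @param labels binary labels (1 = preictal).
#' @param threshold decision threshold (default 0.5).
#' @return An object of class `eval_metrics` with fields `tp`, `fp`, `tn`,
#'   `fn`, `acc`, `sen`, `spe`, `roc_points`, `auc`.
#' @export
compute_metrics <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  n_pos <- tp + fn; n_neg <- tn + fp
  sen <- if (n_pos == 0) { warning("no preictal windows; SEN undefined"); NA_real_ }
         else tp / n_pos
  spe <- if (n_neg == 0) { warning("no interictal windows; SPE undefined"); NA_real_ }
         else tn / n_neg
  if (n_pos > 0 && n_neg > 0) {
    # threshold sweep over sorted unique probabilities (cumulative form)
    ord <- order(probabilities, decreasing = TRUE)
    ps <- probabilities[ord]; ls <- labels[ord]
    cum_tp <- cumsum(ls == 1); cum_fp <- cumsum(ls == 0)
    last_of_tie <- c(ps[-1] != ps[-length(ps)], TRUE)
    tpr <- c(0, cum_tp[last_of_tie] / n_pos)
    fpr <- c(0, cum_fp[last_of_tie] / n_neg)
    auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    roc <- data.frame(fpr = fpr, tpr = tpr)
  } else { auc <- NA_real_; roc <- data.frame(fpr = numeric(), tpr = numeric()) }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 acc = (tp + tn) / length(labels), sen = sen, spe = spe,
                 roc_points = roc, auc = auc),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> ACC %.2f%%  SEN %s  SPE %s  AUC %s  (tp %d fp %d tn %d fn %d)\n",
              100 * x$acc,
              ifelse(is.na(x$sen), "NA", sprintf("%.2f%%", 100 * x$sen)),
              ifelse(is.na(x$spe), "NA", sprintf("%.2f%%", 100 * x$spe)),
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
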