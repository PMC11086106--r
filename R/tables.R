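#' Packaged per-patient CNN results
#'
#' Per-patient ACC/SEN/SPE of the convolutional model under RCV, LOO, Cal1
#' and Cal2 for the two published study cohorts, as shipped with the package.
#' These are inputs to the derivable summary statistics, not outputs of this
#' package's models.
#'
#' @param dataset "chbmit" or "conegliano".
#' @return data.frame, one row per patient.
#' @export
per_patient_table <- function(dataset = c("chbmit", "conegliano")) {
  dataset <- match.arg(dataset)
  utils::read.delim(system.file("extdata",
                                paste0("cnn_per_patient_", dataset, ".tsv"),
                                package = "seizcal"),
                    stringsAsFactors = FALSE)
}

#' Packaged summary statistics
#'
#' The published condition means, standard deviations and repeated-measures
#' F-values (CNN) or means/stds (gradient-boosted baseline), used as the
#' reference that [verify_tables()] recomputes against.
#'
#' @param model "cnn" or "xgb".
#' @return data.frame.
#' @export
summary_table <- function(model = c("cnn", "xgb")) {
  model <- match.arg(model)
  utils::read.delim(system.file("extdata", paste0(model, "_summary.tsv"),
                                package = "seizcal"),
                    stringsAsFactors = FALSE)
}

.metric_columns <- function(df, metric) {
  pre <- c(LOO = "loo", Cal1 = "cal1", Cal2 = "cal2")
  m <- sapply(pre, function(p) df[[paste0(p, "_", tolower(metric))]])
  rownames(m) <- df$id
  m
}

#' Recompute every derivable summary statistic from the per-patient tables
#'
#' From the packaged per-patient results this recomputes, for each cohort
#' and metric: the unweighted condition means and sample standard
#' deviations, the repeated-measures ANOVA F-value over \{LOO, Cal1, Cal2\},
#' the Tukey post hoc p-values, the cohort-level calibration gains (rounded
#' difference of condition means vs LOO), and the two largest per-patient
#' Cal2 accuracy gains. Each recomputed value is paired with the packaged
#' published value and the discrepancy.
#'
#' @return list with elements `cells` (data.frame: dataset, metric,
#'   condition, recomputed mean/std, published mean/std), `anova`
#'   (data.frame: dataset, metric, recomputed F, published F), `tukey`
#'   (data.frame of p-values), `gains` (data.frame of rounded cohort-mean
#'   gains), `patient_gains` (per-patient Cal2 - LOO accuracy gains),
#'   `xgb_gains` (rounded baseline accuracy gains).
#' @export
verify_tables <- function() {
  cells <- list(); anova <- list(); tukey <- list(); gains <- list()
  for (ds in c("chbmit", "conegliano")) {
    df <- per_patient_table(ds)
    pub <- summary_table("cnn")
    pub <- pub[pub$dataset == ds, ]
    for (metric in c("ACC", "SEN", "SPE")) {
      m <- .metric_columns(df, metric)
      pr <- pub[pub$metric == metric, ]
      for (cond in colnames(m)) {
        key <- tolower(cond)
        cells[[length(cells) + 1]] <- data.frame(
          dataset = ds, metric = metric, condition = cond,
          mean = mean(m[, cond]), std = stats::sd(m[, cond]),
          published_mean = pr[[paste0(key, "_mean")]],
          published_std = pr[[paste0(key, "_std")]])
      }
      a <- rm_anova(m)
      anova[[length(anova) + 1]] <- data.frame(
        dataset = ds, metric = metric, f_value = a$f_value,
        p_value = a$p_value, published_f = pr$f_value)
      tk <- tukey_posthoc(m)
      tk$dataset <- ds; tk$metric <- metric
      tukey[[length(tukey) + 1]] <- tk
      for (cond in c("Cal1", "Cal2"))
        gains[[length(gains) + 1]] <- data.frame(
          dataset = ds, metric = metric, condition = cond,
          gain = mean(m[, cond]) - mean(m[, "LOO"]),
          gain_rounded = round(mean(m[, cond]) - mean(m[, "LOO"])))
    }
  }
  # per-patient Cal2 accuracy gains in the second cohort (the two patients
  # with the poorest baselines improve most)
  con <- per_patient_table("conegliano")
  pg <- data.frame(id = con$id, gain_cal2 = con$cal2_acc - con$loo_acc)
  xgb <- summary_table("xgb")
  xa <- xgb[xgb$metric == "ACC", ]
  xgb_gains <- data.frame(
    dataset = rep(xa$dataset, each = 2),
    condition = rep(c("Cal1", "Cal2"), nrow(xa)),
    gain = as.numeric(t(cbind(xa$cal1_mean - xa$loo_mean,
                              xa$cal2_mean - xa$loo_mean))))
  xgb_gains$gain_rounded <- round(xgb_gains$gain)
  list(cells = do.call(rbind, cells), anova = do.call(rbind, anova),
       tukey = do.call(rbind, tukey), gains = do.call(rbind, gains),
       patient_gains = pg, xgb_gains = xgb_gains)
}
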