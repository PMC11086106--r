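#' One-way repeated-measures ANOVA
#'
#' Within-subject analysis of variance for a complete patients x conditions
#' table of one metric. The condition effect is tested against the
#' condition-by-subject interaction: F = MS_condition / MS_(condition x
#' subject) on (c - 1, (c - 1)(n - 1)) degrees of freedom.
#'
#' @param table numeric matrix, rows = patients, columns = conditions;
#'   no missing cells (no imputation is performed).
#' @return An object of class `rm_anova` with `f_value`, `p_value`,
#'   `df_condition`, `df_error`, and the sums of squares.
#' @export
rm_anova <- function(table) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("repeated-measures ANOVA requires a complete table")
  n <- nrow(table); c <- ncol(table)
  if (n < 2 || c < 2) stop("need at least 2 patients and 2 conditions")
  gm <- mean(table)
  ss_cond <- n * sum((colMeans(table) - gm)^2)
  ss_subj <- c * sum((rowMeans(table) - gm)^2)
  ss_tot <- sum((table - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_c <- c - 1; df_e <- (c - 1) * (n - 1)
  ms_c <- ss_cond / df_c; ms_e <- ss_err / df_e
  f <- if (ms_e > 0) ms_c / ms_e else if (ms_c == 0) 0 else Inf
  p <- stats::pf(f, df_c, df_e, lower.tail = FALSE)
  structure(list(f_value = f, p_value = p, df_condition = df_c,
                 df_error = df_e, ss_condition = ss_cond, ss_subject = ss_subj,
                 ss_error = ss_err, ms_error = ms_e, n_subjects = n),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> F(%d, %d) = %.2f, p = %.4g\n",
              x$df_condition, x$df_error, x$f_value, x$p_value))
  invisible(x)
}

#' Tukey HSD post hoc tests for a repeated-measures design
#'
#' Pairwise comparisons of condition means using the within-subject error
#' term from [rm_anova()]: the studentized range statistic
#' q = |m_i - m_j| / sqrt(MS_error / n) referred to the studentized-range
#' distribution with the interaction degrees of freedom.
#'
#' @param table numeric matrix, rows = patients, columns = conditions
#'   (column names label the comparisons).
#' @return data.frame with columns `comparison`, `diff`, `q`, `p_value`.
#' @export
tukey_posthoc <- function(table) {
  table <- as.matrix(table)
  a <- rm_anova(table)
  cm <- colMeans(table)
  cn <- colnames(table)
  if (is.null(cn)) cn <- paste0("cond", seq_along(cm))
  c <- length(cm); n <- a$n_subjects
  se <- sqrt(a$ms_error / n)
  rows <- list()
  for (i in seq_len(c - 1)) for (j in (i + 1):c) {
    d <- cm[j] - cm[i]
    q <- if (se > 0) abs(d) / se else if (d == 0) 0 else Inf
    p <- if (se > 0) stats::ptukey(q, c, a$df_error, lower.tail = FALSE)
         else as.numeric(d != 0) * 0 + as.numeric(d == 0)
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste(cn[i], cn[j], sep = "-"),
      diff = d, q = q, p_value = p)
  }
  do.call(rbind, rows)
}

#' Summarize per-patient results across conditions
#'
#' Unweighted patient means with sample standard deviations (n - 1), plus
#' per-patient gains of every condition over the leave-one-out baseline when
#' a column named "LOO" is present. Missing (NA) values shrink the averaging
#' denominator with a warning rather than being imputed.
#'
#' @param table numeric matrix, rows = patients, columns = conditions.
#' @return list with `mean`, `std` (named per condition) and `gains`
#'   (patients x conditions matrix of differences vs LOO, or NULL).
#' @export
summarize_conditions <- function(table) {
  table <- as.matrix(table)
  if (anyNA(table))
    warning("missing per-patient values; summaries use available patients only")
  m <- colMeans(table, na.rm = TRUE)
  s <- apply(table, 2, stats::sd, na.rm = TRUE)
  gains <- NULL
  if ("LOO" %in% colnames(table))
    gains <- table - table[, "LOO"]
  list(mean = m, std = s, gains = gains)
}
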