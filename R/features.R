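#' Hjorth parameters of a single-channel window
#'
#' Activity is the signal variance; mobility the ratio of the standard
#' deviation of the first difference to that of the signal; complexity the
#' mobility of the first difference over the mobility of the signal. For a
#' unit sinusoid of angular frequency w per sample: activity 0.5, mobility
#' 2 sin(w/2), complexity 1. Constant windows return (0, 0, 0).
#'
#' @param x numeric vector, length >= 3.
#' @return Named numeric vector `activity`, `mobility`, `complexity`.
#' @export
hjorth_parameters <- function(x) {
  stopifnot(length(x) >= 3)
  v0 <- .popvar(x)
  if (v0 <= 0) return(c(activity = 0, mobility = 0, complexity = 0))
  d1 <- diff(x)
  v1 <- .popvar(d1)
  mob <- sqrt(v1 / v0)
  if (v1 <= 0) return(c(activity = v0, mobility = 0, complexity = 0))
  d2 <- diff(d1)
  v2 <- .popvar(d2)
  cmp <- sqrt(v2 / v1) / mob
  c(activity = v0, mobility = mob, complexity = cmp)
}

.popvar <- function(x) { m <- mean(x); mean((x - m)^2) }

#' Normalized spectral entropy
#'
#' Shannon entropy of the periodogram normalized to a probability
#' distribution, divided by log of the number of frequency bins, giving a
#' value in \[0, 1\]: near 0 for a pure tone, near 1 for white noise (the
#' exact white-noise expectation is 1 - (1 - gamma)/log(nbins), approaching
#' 1 with window length). All-zero windows return 0 by convention.
#'
#' @param x numeric vector, length >= 8.
#' @param sample_rate_hz sampling rate (shapes the frequency axis only).
#' @return A number in \[0, 1\].
#' @export
spectral_entropy <- function(x, sample_rate_hz = 128) {
  n <- length(x)
  stopifnot(n >= 8)
  spec <- Mod(stats::fft(x))^2
  nb <- n %/% 2
  p <- spec[2:(nb + 1)]        # positive frequencies, DC excluded
  tot <- sum(p)
  if (tot <= 0) return(0)
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(nb)
}

# canonical EEG bands (Hz)
.eeg_bands <- function() list(delta = c(0.5, 4), theta = c(4, 8),
                              alpha = c(8, 13), beta = c(13, 30),
                              gamma = c(30, 45))

#' Band power of a single-channel window
#'
#' Mean periodogram power within each frequency band.
#'
#' @param x numeric vector.
#' @param sample_rate_hz sampling rate in Hz.
#' @param bands named list of `c(lo, hi)` band edges; defaults to the
#'   canonical delta/theta/alpha/beta/gamma bands.
#' @return Named numeric vector of band powers.
#' @export
band_power <- function(x, sample_rate_hz, bands = .eeg_bands()) {
  n <- length(x)
  spec <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * sample_rate_hz / n
  half <- 2:(n %/% 2 + 1)
  f <- freqs[half]; s <- spec[half]
  vapply(bands, function(b) {
    sel <- f >= b[1] & f < b[2]
    if (!any(sel)) 0 else mean(s[sel])
  }, 0)
}

.feature_stat_block <- function(x) {
  m <- mean(x); v <- .popvar(x); s <- sqrt(v)
  sk <- if (s > 0) mean((x - m)^3) / s^3 else 0
  ku <- if (s > 0) mean((x - m)^4) / s^4 else 0
  c(mean = m, variance = v, std = s, skewness = sk, kurtosis = ku)
}

.feature_shape_block <- function(x) {
  c(line_length = sum(abs(diff(x))),
    zero_cross_rate = mean(diff(sign(x)) != 0),
    rms = sqrt(mean(x^2)),
    iqr = stats::IQR(x))
}

#' The 53-feature manifest
#'
#' @return data.frame with columns `name`, `family`, `input` describing each
#'   of the 53 features in extraction order.
#' @export
feature_manifest <- function() {
  path <- system.file("extdata", "feature_manifest.tsv", package = "seizcal")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Extract the 53-feature vector from one window
#'
#' Deterministic, stateless engineered-feature summary of a preprocessed,
#' standardized window, combining every standard family: time-domain moments,
#' Hjorth parameters, spectral entropy, absolute and relative band power with
#' two band-ratio features on the channel-averaged signal; the same moment /
#' Hjorth / entropy / shape blocks on its first difference; per-hemisphere
#' log band powers and their asymmetries (left = odd channel positions,
#' right = even, a montage-agnostic split); and line length, zero-crossing
#' rate, RMS and interquartile range. The exact composition is frozen in
#' `inst/extdata/feature_manifest.tsv`.
#'
#' @param window channels x samples numeric matrix.
#' @param sample_rate_hz sampling rate in Hz.
#' @return Named numeric vector of exactly 53 finite values.
#' @export
extract_features <- function(window, sample_rate_hz = 128) {
  window <- as.matrix(window)
  x <- colMeans(window)                      # channel-averaged signal
  d <- diff(x)
  bands <- .eeg_bands()
  bp <- band_power(x, sample_rate_hz, bands)
  tot <- sum(bp)
  rel <- if (tot > 0) bp / tot else rep(0, length(bp))
  eps <- 1e-12
  nch <- nrow(window)
  left <- colMeans(window[seq(1, nch, by = 2), , drop = FALSE])
  right <- if (nch >= 2) colMeans(window[seq(2, nch, by = 2), , drop = FALSE])
           else left
  bpl <- band_power(left, sample_rate_hz, bands)
  bpr <- band_power(right, sample_rate_hz, bands)
  out <- c(
    .feature_stat_block(x),                                     # 5
    hjorth_parameters(x),                                       # 3
    spectral_entropy = spectral_entropy(x, sample_rate_hz),     # 1
    stats::setNames(bp, paste0("abs_power_", names(bands))),    # 5
    stats::setNames(rel, paste0("rel_power_", names(bands))),   # 5
    ratio_theta_alpha = bp[["theta"]] / (bp[["alpha"]] + eps),  # 1
    ratio_beta_slow = bp[["beta"]] / (bp[["delta"]] + bp[["theta"]] + eps), # 1
    stats::setNames(log(bpl + eps), paste0("left_logpower_", names(bands))),  # 5
    stats::setNames(log(bpr + eps), paste0("right_logpower_", names(bands))), # 5
    stats::setNames(log((bpl + eps) / (bpr + eps)),
                    paste0("asym_", names(bands))),             # 5
    .feature_shape_block(x),                                    # 4
    stats::setNames(.feature_shape_block(d),
                    paste0("diff_", names(.feature_shape_block(d)))), # 4
    stats::setNames(.feature_stat_block(d),
                    paste0("diff_", names(.feature_stat_block(d)))),  # 5
    stats::setNames(hjorth_parameters(d),
                    paste0("diff_", names(hjorth_parameters(d)))),    # 3
    diff_spectral_entropy = spectral_entropy(d, sample_rate_hz) # 1
  )
  out[!is.finite(out)] <- 0
  stopifnot(length(out) == 53)
  out
}

#' Extract features for every window in a set
#'
#' @param ws a `window_set`.
#' @return data.frame: 53 feature columns plus provenance columns `label`,
#'   `patient_id`, `seizure_index`.
#' @export
extract_feature_table <- function(ws) {
  n <- dim(ws$windows)[1]
  feats <- matrix(0, n, 53)
  for (i in seq_len(n))
    feats[i, ] <- extract_features(ws$windows[i, , , drop = TRUE],
                                   ws$sample_rate_hz)
  colnames(feats) <- names(extract_features(
    matrix(sin(seq_len(2 * 64)), 2), ws$sample_rate_hz))
  df <- as.data.frame(feats)
  df$label <- ws$labels
  df$patient_id <- ws$patient_ids
  df$seizure_index <- ws$seizure_indices
  df
}
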