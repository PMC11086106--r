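// IIR filtering primitives and the synthetic-recording synthesizer.
// Filter coefficients are designed in R (signal::butter and a biquad notch);
// these routines only apply them, in direct form II transposed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace Rcpp;

namespace {

void iir_apply(const std::vector<double>& b, const std::vector<double>& a,
               const double* x, double* y, size_t n) {
  const size_t nb = b.size(), na = a.size();
  const size_t ns = std::max(nb, na) - 1;
  std::vector<double> z(ns, 0.0);
  for (size_t i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (ns ? z[0] : 0.0);
    for (size_t k = 1; k <= ns; ++k) {
      double zk = (k < ns) ? z[k] : 0.0;
      double bb = (k < nb) ? b[k] : 0.0;
      double aa = (k < na) ? a[k] : 0.0;
      z[k - 1] = bb * xi - aa * yi + zk;
    }
    y[i] = yi;
  }
}

std::vector<double> as_std(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

} // namespace

// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  NumericVector y(x.size());
  iir_apply(as_std(b), as_std(a), x.begin(), y.begin(), x.size());
  return y;
}

// Zero-phase filtering: forward pass, backward pass, with reflected-edge
// padding to suppress startup transients.
// [[Rcpp::export(name = ".iir_filtfilt")]]
NumericVector iir_filtfilt(NumericVector b, NumericVector a, NumericVector x) {
  const size_t n = x.size();
  const size_t npad = std::min(n - 1, (size_t)1536);
  std::vector<double> ext(n + 2 * npad);
  for (size_t i = 0; i < npad; ++i)
    ext[i] = 2 * x[0] - x[npad - i];
  std::copy(x.begin(), x.end(), ext.begin() + npad);
  for (size_t i = 0; i < npad; ++i)
    ext[npad + n + i] = 2 * x[n - 1] - x[n - 2 - i];
  std::vector<double> tmp(ext.size());
  auto bb = as_std(b); auto aa = as_std(a);
  iir_apply(bb, aa, ext.data(), tmp.data(), ext.size());
  std::reverse(tmp.begin(), tmp.end());
  iir_apply(bb, aa, tmp.data(), ext.data(), ext.size());
  std::reverse(ext.begin(), ext.end());
  NumericVector y(n);
  std::copy(ext.begin() + npad, ext.begin() + npad + n, y.begin());
  return y;
}

// Synthesize one multichannel recording: per frequency band, band-limited
// Gaussian noise (a shared across-channel series mixed with channel-specific
// series), each normalized to unit variance and scaled by per-channel band
// gains; the designated bands are rescaled by `effect` over the preictal
// span [pre_start, pre_end); an ictal span carries a high-amplitude 3 Hz
// oscillation; white noise is added at `noise_floor`.
//
// band_b / band_a: list of filter coefficient vectors per band.
// gains: n_ch x n_band. effect: length n_band multiplier (1 = untouched).
// Sample indices are 0-based; spans are half-open.
// [[Rcpp::export(name = ".synth_recording")]]
NumericMatrix synth_recording(int n_ch, int n_samples, List band_b,
                              List band_a, NumericMatrix gains,
                              double mixing, double noise_floor,
                              NumericVector effect,
                              double pre_start, double pre_end,
                              double ictal_start, double ictal_end,
                              double ictal_amp, double sample_rate,
                              int seed) {
  const int nband = band_b.size();
  const int warm = 1024;                  // discarded filter warm-up
  const size_t L = (size_t)n_samples, Lw = L + warm;
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  NumericMatrix out(n_ch, n_samples);

  std::vector<std::vector<double>> bb(nband), aa(nband);
  for (int k = 0; k < nband; ++k) {
    bb[k] = as_std(band_b[k]); aa[k] = as_std(band_a[k]);
  }
  std::vector<double> noise(Lw), filt(Lw);

  auto make_band = [&](int k, std::vector<double>& dst) {
    for (size_t i = 0; i < Lw; ++i) noise[i] = gauss(rng);
    // cascade the band filter twice: steeper skirts keep each component's
    // power inside its nominal band (single-pass skirts leak enough across
    // adjacent bands to bias band-power contrasts)
    iir_apply(bb[k], aa[k], noise.data(), filt.data(), Lw);
    std::swap(noise, filt);
    iir_apply(bb[k], aa[k], noise.data(), filt.data(), Lw);
    double s1 = 0, s2 = 0;
    for (size_t i = warm; i < Lw; ++i) { s1 += filt[i]; s2 += filt[i] * filt[i]; }
    double m = s1 / L;
    double sd = std::sqrt(std::max(s2 / L - m * m, 1e-12));
    dst.resize(L);
    for (size_t i = 0; i < L; ++i) dst[i] = (filt[i + warm] - m) / sd;
  };

  // shared across-channel band series
  std::vector<std::vector<double>> shared(nband);
  for (int k = 0; k < nband; ++k) make_band(k, shared[k]);

  const double wsh = std::sqrt(mixing), wch = std::sqrt(1.0 - mixing);
  const size_t p0 = (size_t)std::max(0.0, pre_start),
               p1 = (size_t)std::min((double)L, pre_end);
  std::vector<double> chan(L);
  for (int c = 0; c < n_ch; ++c) {
    double* row = &out(c, 0);        // note: row access is strided
    std::vector<double> acc(L, 0.0);
    for (int k = 0; k < nband; ++k) {
      make_band(k, chan);
      const double g = gains(c, k), e = effect[k];
      const std::vector<double>& sh = shared[k];
      for (size_t i = 0; i < L; ++i) {
        double v = g * (wsh * sh[i] + wch * chan[i]);
        if (e != 1.0 && i >= p0 && i < p1) v *= e;
        acc[i] += v;
      }
    }
    for (size_t i = 0; i < L; ++i)
      acc[i] += noise_floor * gauss(rng);
    // ictal marker: large-amplitude slow oscillation with jitter
    if (ictal_end > ictal_start) {
      const size_t i0 = (size_t)std::max(0.0, ictal_start),
                   i1 = (size_t)std::min((double)L, ictal_end);
      const double w = 2.0 * M_PI * 3.0 / sample_rate;
      for (size_t i = i0; i < i1; ++i)
        acc[i] += ictal_amp * (std::sin(w * (double)(i - i0))
                               + 0.2 * gauss(rng));
    }
    for (size_t i = 0; i < L; ++i) row[i * n_ch] = acc[i];
  }
  return out;
}
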