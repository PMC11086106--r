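---
title: "Patient-independent seizure forecasting with model calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-independent seizure forecasting with model calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Seizure forecasting asks whether an impending epileptic seizure can be read
from scalp EEG before it starts. `seizcal` frames it as the field's standard
binary window-classification task: 5-second multichannel windows are labeled
**preictal** — drawn from the 15 minutes that end exactly at seizure
onset — or **interictal** — baseline activity that ends at least 4 hours
before the preictal window begins. The package's reason to exist is not the
classifier itself but the *validation* question: randomized cross-validation
(RCV) mixes every patient's windows across training and test folds and
therefore rewards memorizing patient identity; leave-one-patient-out (LOO)
validation, the clinically honest protocol, removes the target patient
entirely and typically collapses performance to near chance. Between the two
sits **calibration**: fine-tune the patient-independent LOO model on one
(Cal1) or two (Cal2) seizures recorded from the new patient, then test on
that patient's remaining seizures. The package implements the full pipeline
— ingestion, labeling, preprocessing, two classifiers, the four validation
conditions, and the evaluation statistics — plus a synthetic cohort
generator that reproduces the statistical structure the comparison needs.

## Eligibility and labeling rules

A seizure is usable only when enough clean history precedes it. The
eligibility lookback requires strictly more than `gap_hours + preictal_min`
(4 h 15 min at defaults) of contiguous recorded, seizure-free time before
onset. A plain "more than four hours before onset" rule would be
self-defeating: after carving out the 15-minute preictal window and the
4-hour buffer, a seizure with exactly four hours of history would have no
interictal time left. Recording gaps and earlier ictal spans both cut the
lookback, so "4 hours" always means 4 hours of *elapsed, recorded, normal*
brain activity, never 4 hours of file time.

Given an eligible seizure, `label_seizure()` emits the preictal segment
`[onset - 15 min, onset]` and an interictal segment ending 4 hours before
the preictal start, extending backwards up to 60 minutes, truncated at the
recording start, at a gap, or at the previous seizure's offset. The
interictal segment is then undersampled to a random contiguous 15 minutes
(`undersample_interictal()`, uniform start, seeded) so both classes
contribute the same duration — after 5-second windowing, 180 windows each.
One labeled pair is produced per eligible seizure, not per patient, because
calibration needs per-seizure units. Patients with a single seizure are
used only to train models; leave-out targets need at least two.

## Preprocessing and the leakage rules

The fixed order is: filter → decimate → cut segments → window →
standardize. Filtering happens once per continuous recording at the native
256 Hz — never per window, which would put an edge transient inside every
window. The chain is: notch biquads (quality 30) at 50 and 100 Hz, a
zero-phase 4th-order Butterworth high-pass at 1 Hz, a low-pass at 125 Hz,
and decimation to 128 Hz behind an eighth-order anti-alias low-pass at
0.9 of the target Nyquist. The 125 Hz low-pass sits above the
post-decimation Nyquist (64 Hz); it is kept because the published chain
names it, and the decimator's own anti-alias filter is what actually
bounds the band. Windows are non-overlapping: overlapping windows would
place near-duplicates of the same signal on both sides of an RCV fold
split and inflate the very scores the package is designed to deflate.

Standardization is where information leaks most easily, so who supplies
the per-channel mean and standard deviation is part of each protocol:

* **RCV** — statistics of the training split of each fold only.
* **LOO** — each training patient standardized with their own statistics;
  the test patient with the *pooled* training statistics (unweighted mean
  of per-patient means, root-mean-square of per-patient standard
  deviations, so every patient counts equally regardless of recording
  length).
* **Calibration** — statistics of the calibration seizures' windows,
  applied to the entire target signal, calibration and test alike.

Statistics are computed on the continuous preprocessed signal scale (not
per window), standard deviations are floored at 1e-6 µV so a dead channel
cannot produce infinities, and `standardize()` refuses double application
via a provenance flag. `audit_leakage()` re-checks every LOO/calibration
run from recorded provenance.

## The convolutional classifier

The network takes a raw standardized window (channels × 640 samples) and
applies six blocks of convolution → batch normalization → ReLU → max
pooling → dropout, with kernels 16@1×3, 32@1×3, 64@1×5, 96@1×7, 128@5×5,
256@3×3 (valid padding, stride 1, no conv bias — the batch-norm shift
absorbs it), pools 1×2, 1×2, 1×5, 1×2, 2×2, 2×2, and dropout 0.2 except
0.5 in the last block. Kernel height spans channels, so the early 1×k
kernels are purely temporal and the late square kernels exploit
interchannel correlation. For both 22- and 20-channel montages the stack
flattens to 768 nodes (`conv_stack_output_shape()` traces this
analytically and the test suite checks the trace against instantiated
networks), followed by dense ReLU layers of 128 and 32 units and a sigmoid
output. Dense-layer activations are not specified in the source
description; ReLU is assumed and documented here. Training is Adam on
binary cross-entropy; the default learning rate 2e-4 and batch size 64 are
declared package choices from the plausible grid, since the winning values
of the original hyperparameter search were not reported. Early stopping
holds out a label-stratified 10% of the training windows and stops after 5
epochs without validation-loss improvement (the original recipe names only
"an early-stopping criterion"; these constants are ours). The
implementation is the package's own (RcppArmadillo, single-precision,
im2col + GEMM); its backward pass is verified against central finite
differences in the test suite.

Fine-tuning (`fine_tune()`) continues optimization from the stored LOO
checkpoint — never re-initializing — at one tenth of the training rate for
at most 20 epochs, on the calibration windows only, with no validation
holdout because one seizure yields only a few hundred windows. A pooled
`cal-mode` (replaying original training windows) is deliberately not the
default: the intent of calibration is a minutes-scale adaptation step.
The classification threshold on the sigmoid output is 0.5.

## The engineered-feature baseline

The comparison arm is an XGBoost classifier over exactly 53 deterministic
features per window, frozen in `inst/extdata/feature_manifest.tsv`: on the
channel-averaged signal, the five time-domain moments, the three Hjorth
parameters, normalized spectral entropy, absolute and relative power in the
five canonical bands and two band ratios; per-hemisphere log band powers
and asymmetries (hemispheres = odd/even channel positions, a
montage-agnostic split); line length, zero-crossing rate, RMS and
interquartile range on the signal and on its first difference; and the
moments, Hjorth parameters and spectral entropy of the first difference.
The exact historical feature list is not recoverable from the source
description (it defers to an earlier reference), so the contract here is:
documented, deterministic, exactly 53, containing every named family —
equality with the published baseline numbers is not claimed. Baseline
calibration is continued boosting: extra trees fit to the calibration
windows with the original ensemble frozen, mirroring the warm-start
protocol of the CNN; full retraining is available as an option.

## Evaluation statistics

`compute_metrics()` reports accuracy, sensitivity and specificity from the
thresholded confusion counts, the ROC by sweeping the threshold over the
sorted unique probabilities, and the trapezoidal AUC. When a test set lacks
a class, the undefined rate propagates as `NA` (with a warning) and shrinks
the averaging denominator — reporting 0 would silently punish the mean.
Condition summaries are unweighted patient means with n−1 standard
deviations. Condition comparisons use a one-way repeated-measures ANOVA
(condition effect tested against the condition × subject interaction) and
Tukey HSD post hoc tests on the within-subject error term via the
studentized range distribution. `verify_tables()` recomputes every
derivable summary cell, F-value and gain from the packaged per-patient
tables; the recomputation matches all printed cells to two decimals (one
final-digit rounding difference arises because the per-patient inputs are
themselves printed rounded). The packaged Tukey p-value table does not
reproduce exactly under either plausible error-term convention, so the test
suite asserts the published inequalities (significant vs baseline,
non-significant between Cal1 and Cal2) rather than the printed values.

## The synthetic cohort generator

`generate_cohort()` produces what the validation comparison presumes but
no public fixture provides: cohorts where cross-patient transfer is hard
and calibration demonstrably helps. Each patient's signal is a sum of
band-limited Gaussian noise in the five canonical bands with per-patient
log-uniform band gains (spectral signatures), a shared across-channel
component (default mixing 0.5) so interchannel correlation exists for the
2-D convolution stages, and a white-noise floor. During the 15 minutes
before each onset the designated bands are rescaled by `preictal_effect`;
`shared_effect_fraction` splits that effect (on the log scale) between one
globally shared band and one patient-specific band. The fraction is the
covariate-shift dial: at 1 a band-power threshold rule transfers across
patients, at 0 it transfers at chance while staying learnable within a
patient — both verified in the test suite. Ictal spans carry a
high-amplitude 3 Hz marker; their content is otherwise irrelevant because
ictal data is never a class. The generator makes no attempt at waveform
morphology (spikes, eye blinks, EMG artifacts) or circadian structure:
passing tests demonstrate that the *pipeline logic and statistical
machinery* behave correctly under the assumed spectral structure, not that
any classifier will reach a particular accuracy on clinical EEG.

Defaults mirror the study conditions: 20 channels at 256 Hz, at least
4.5 hours of pre-seizure recording (comfortably beyond the 4 h 15 min
eligibility lookback), amplitude effect 2 (power ×4), and a 60-second
unrecorded gap between per-seizure files, which also exercises the rule
that segments may not span gaps.

## The scaled end-to-end study

The acceptance suite runs the whole design — RCV, LOO, Cal1, Cal2, the
ANOVA — on a desk-scale cohort: 8 patients, 3 seizures each, 30-minute
pre-seizure spans, 12 channels (the narrowest montage the conv stack
admits), with proportionally shrunk labeling windows (preictal 2 min, gap
15 min, interictal up to 10 min undersampled to 2 min; the generator's
simulated preictal state stays at 15 min, so it covers the labeled
preictal window and stops well short of the interictal one) and a small
fixed training budget: learning rate 5e-3 from the plausible grid, batch
32, 4 epochs for RCV and 1 for the LOO transfer baseline, 8 fine-tuning
epochs at a tenth of the rate, no early-stop holdout at this size.
Expected shape, asserted as properties rather than magnitudes: mean
accuracy ordered RCV > Cal2 ≥ Cal1 > LOO; Cal1 above LOO for at least 90%
of patients; repeated-measures ANOVA over {LOO, Cal1, Cal2} rejecting at
p < 0.05.

Two generator design points deserve emphasis. First, the patient-specific
part of the preictal effect is a spectral *redistribution* — one private
band up, another down by the same factor, assigned round-robin across
patients — rather than a plain amplification: a uniform power increase
would itself be a patient-independent cue and would let a cross-patient
model succeed for the wrong reason. Second, per-seizure band-gain jitter
(default spread 1.2) models within-patient variability between seizure
events; it is what separates Cal2 from Cal1 (two calibration seizures
average over the wobble) and keeps single-seizure calibration below the
pooled-data ceiling, while remaining small relative to patient
specificity so that calibrating on one seizure still helps every patient.

## Numerical and degenerate-input decisions

* Hjorth parameters of a constant window are defined as (0, 0, 0); spectral
  entropy of an all-zero window is 0.
* Band powers are periodogram means over half-open bins `[lo, hi)`; guards
  replace any non-finite feature with 0.
* EDF is written with 1-second records, per-channel physical ranges and
  16-bit quantization; write-then-read agrees within one quantization step.
  The reader converts mV/V to µV on ingestion.
* The undersampling draw, fold assignment, second-calibration-seizure
  draw, parameter initialization, shuffling and dropout are all seeded;
  per-patient generator sub-seeds are derived deterministically from the
  master seed and kept below 2^31.
* Batch normalization needs at least two samples; trailing minibatches of
  size one are skipped.

## Known limitations

* Synthetic signals validate contracts and directions, not clinical
  accuracy; absolute metric values on real EEG are out of scope.
* The 53-feature list is a documented reconstruction of the named feature
  families, not the historical list.
* Seizure-onset alarm logic (prediction horizons, false alarms per hour)
  is out of scope: evaluation is window classification only.
* The EDF reader covers the plain EDF layout used by public scalp-EEG
  archives (uniform rate across channels); EDF+ annotations embedded in
  signal streams are not parsed — annotations come from the summary or CSV
  sidecar dialects.
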