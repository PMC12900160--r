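---
title: "Models and methods behind psgcomorb"
author: "psgcomorb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psgcomorb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(psgcomorb)
```

## The problem

Obstructive sleep apnea (OSA) rarely travels alone: hypertension, diabetes
mellitus and chronic airway disease (asthma/COPD) co-occur with it so often
that a polysomnography (PSG) recording plausibly carries information about
all three. `psgcomorb` implements a complete pipeline that asks exactly that
question of two PSG channels — pulse-oximetry oxygen saturation (SpO2) and
nasal airflow (FP0) — fused with routine clinical variables (age, gender,
BMI, apnea–hypopnea index, heart rate), and answers it as a multi-label
classification problem with a three-unit sigmoid output.

Because clinical PSG recordings cannot be redistributed, the package treats
a synthetic cohort simulator as a first-class component. Every downstream
stage — preprocessing, event detection, feature engineering, model training,
evaluation — is validated against the simulator's exact ground truth.

## The synthetic cohort

`cohort_config()` / `generate_patient()` produce overnight two-channel
recordings with scheduled apnea–desaturation events. One event is described
by four markers: airflow cessation onset `t1` and offset `t2` on the airflow
channel, desaturation onset `t3` and recovery end `t4` on the SpO2 channel.

* **SpO2**: a per-patient baseline (truncated normal, mean 96 %, SD 1,
  bounds 94–98 %) with, per event, a piecewise-linear excursion — a fall at
  the event's slope (%/s) down to `baseline − depth`, a plateau, and a
  linear recovery ending exactly at `t4`. The piecewise-linear shape makes
  depth and slope analytically checkable.
* **FP0**: a 0.25 Hz sinusoid (15 breaths/minute) whose amplitude envelope
  collapses to 5 % of baseline between `t1` and `t2`, with 2 s ramps. This
  is the simplest waveform that exercises amplitude-based cessation
  detection.
* **Noise**: additive Gaussian, SD 0.3 % on SpO2 and 5 % of the breathing
  amplitude on FP0 — small relative to the 3 % desaturation criterion.
* **Scheduling**: events/hour are drawn from a truncated log-normal whose
  mean (~32) and spread match an adult sleep-clinic population; onsets keep
  a 30 s minimum spacing and events never overlap. A schedule that cannot
  fit (rate × duration too large for the event footprints) raises an error
  rather than silently squeezing events together. The ground-truth AHI is
  the scheduled count divided by the duration, exactly.
* **Event morphology**: template means per patient (cessation ≈ 50 s,
  onset delay t3−t1 ≈ 15 s, recovery delay t4−t2 ≈ 13 s, depth ≈ 6.5 %,
  slope ≈ 0.24 %/s) with within-patient variation. One caveat worth
  stating: published per-patient summary tables of this kind are not always
  internally consistent with the additive identity
  `(t4 − t3) = (t2 − t1) + (t4 − t2) − (t3 − t1)`; the generator samples
  cessation duration, the two delays, depth and slope, and lets the
  desaturation duration be implied by the identity.
* **Labels**: a logistic model on standardized covariates and the patient's
  latent event morphology. Hypertension loads positively on age, BMI and
  AHI; each label also *shifts* the patient's desaturation depth and slope,
  so the comorbidity structure is imprinted on the signals themselves, not
  just the clinical table. Intercepts are calibrated by Gauss–Hermite
  quadrature so marginal prevalences hit their targets (≈ 0.55/0.45/0.45,
  leaving roughly one patient in six label-free). Coefficient scales were
  set so each label's ideal (Bayes) one-vs-rest AUC is ≈ 0.72–0.75, the
  discriminability regime this modelling framework targets; a per-label
  logistic fit on the engineered features of a 400-patient cohort reaches
  macro AUC ≈ 0.73, confirming the calibration.

What the simulator does *not* emulate: sleep staging and arousals, central
vs obstructive event morphology, oximeter averaging artifacts, inter-night
variability, and real covariate–morphology dependence beyond the stated
logistic structure. Green tests therefore demonstrate algorithmic
correctness and recoverability of known structure — not clinical
performance on real recordings.

## Preprocessing

`preprocess_patient()` runs: resample → repair → filter → differentiate →
window.

* **Resampling** to 5 Hz by linear interpolation (masked samples stay
  masked). 5 Hz preserves desaturation/airflow shape while keeping windows
  small.
* **Artifact repair**: SpO2 samples outside 50–100 %, non-finite samples
  and isolated spike excursions (a change faster than 4 %/s immediately
  followed by a fast change in the opposite direction — a monotone
  physiological desaturation never shows this signature) are invalidated.
  Invalid runs ≤ 5 s are linearly interpolated; longer runs are masked
  (`NA`) and excluded from event detection, because interpolating across a
  whole event would fabricate physiology. Detection and interpolation are
  iterated to a fixpoint so the operation is idempotent. Airflow baseline
  drift is removed once by subtracting a 30 s rolling median.
* **Filtering**: zero-phase 4th-order Butterworth low-pass (0.5 Hz SpO2,
  1.0 Hz FP0) followed by a 5-sample moving average. The filter runs on a
  mean-removed, odd-reflection-padded copy: `filtfilt` starts from zero
  initial conditions and would otherwise ring at the record edges.
* **Derivative**: Savitzky–Golay first derivative (window 11 samples,
  order 3), giving the model's second input channel in %/s.
* **Windows**: 60 s windows, 30 s stride — long enough to contain one full
  event (typical event spans are 20–60 s), with `floor((T−L)/S)+1` windows
  and the trailing remainder dropped. Windows touching masked samples are
  flagged and excluded from training.

## Event detection and features

* **Desaturations**: local baseline = rolling maximum of the preceding
  100 s. Candidate events are runs below `baseline − 1 %` reaching at least
  3 % depth for at least 10 s. Onset/recovery markers are then extrapolated
  back to the baseline using the local limb slope (estimated from the
  crossings of two levels 1 % apart), so `t3`/`t4` locate the true start
  and end of the excursion rather than the threshold crossing; the fall end
  is the first arrival at the nadir level, which keeps the slope estimate
  `depth / (nadir time − t3)` unbiased in the presence of a flat plateau.
  On noiseless simulations all four markers are recovered within 1 s and
  detection precision and recall are both 1.0.
* **Cessations**: breathing-amplitude envelope = centred rolling maximum of
  |FP0| over 5 s (≥ one breathing cycle); local baseline amplitude = rolling
  median of the envelope over 120 s, floored at 75 % of its global 95th
  percentile so dense event clusters cannot drag the baseline down. A
  cessation is a run with envelope below 10 % of baseline (the standard
  ≥ 90 % amplitude-reduction criterion) for ≥ 10 s, with edges corrected
  for the envelope half-window.
* **Pairing**: greedy, causal, one-to-one — each cessation claims the
  earliest unclaimed desaturation with `t3 ∈ [t1, t1 + 60 s]`. 60 s is
  permissive (observed onset delays are ≤ ~25 s) without allowing
  cross-event leakage given the 30 s spacing.
* **Features**: the 11-column per-patient vector — five clinical variables
  plus six event statistics (mean onset delay, mean recovery delay, mean
  cessation duration, mean desaturation duration, mean depth, mean fall
  slope). AHI is taken from the clinical table rather than recomputed from
  detected events, matching how such tables are built; the detected event
  rate is available separately. Patients without paired events keep their
  row (median-imputed on the training subset) so the fusion model still
  sees their signals. Z-scoring is fit on the training split only and
  `Gender` passes through unscaled.

## Cohort statistics

`compare_groups()` reproduces the classical baseline table: per variable,
group means ± SD, absolute Cohen's d with the pooled SD, and a one-sided
Welch (unequal-variance) test taken in the direction of the observed
difference. The one-sided Welch convention was chosen because it reproduces
published p-values computed from group summaries of this kind, where pooled
or two-sided variants do not; recomputing effect sizes from the bundled
144-patient reference summaries matches all 44 printed values within 0.01.
No multiple-testing correction is applied by default (mirroring the usual
presentation of such tables); `p_adjust = "BH"` enables
Benjamini–Hochberg. AHI severity strata use the standard clinical cut-offs
<5 / 5–15 / 15–30 / ≥30 events/h.

## The multi-branch 1D-CNN

Three convolutional branches (SpO2, SpO2 derivative, FP0) each apply two
same-padding stride-1 convolution blocks (16 then 32 filters, kernel 7,
batch normalization, ReLU, dropout 0.3) followed by global average pooling;
a clinical branch passes the 11 normalized features through a 32-unit dense
layer. The concatenated embedding feeds a 64-unit dense layer and a 3-unit
sigmoid head. The loss is class-weighted binary cross-entropy with
`w_j = (N − n_j)/n_j` (a focal variant is config-exposed because both
weighting schemes are plausible under class imbalance); optimization is
Adam (default lr 1e-3, batch 32), with early stopping on validation macro
AUC-PR and best-epoch restoration. Patient probability is the mean of the
patient's window probabilities, thresholded at 0.5 with no per-label
threshold tuning.

Since no deep-learning framework is part of this package's dependency
surface, the network is implemented twice: a pure-R reference path
(vectorised im2col convolutions through BLAS) and a fused C++ training step
(RcppArmadillo) used by default. The two paths agree to ~1e-15 on
probabilities and gradients, and the analytic gradients are verified
against numerical differentiation; the R path is the correctness oracle,
the C++ path the speed route. An optional average-pooling factor between
the two convolution blocks (`pool`, default 1 = the stride-1 reference
architecture) trades temporal resolution of the second block for compute;
the property-test suite uses `pool = 4`.

Determinism: initialization, batch order and dropout masks are all driven
by the configured seed (dropout masks in the C++ path use a dedicated
generator seeded from the R stream, so both paths are individually
reproducible).

## Evaluation

`mlc_eval` implements the full multi-label suite: per-label
accuracy/precision/recall/F1 with macro, micro and support-weighted
aggregation; subset, flat and partial (Jaccard) accuracy; Hamming loss
(identically `1 − flat accuracy`); one-vs-rest trapezoidal AUC-ROC and
step-wise average precision, macro-averaged.

Conventions worth making explicit:

* Zero-denominator ratios are 1 in the vacuous case (no positives exist
  and none were predicted) and 0 otherwise, which keeps perfect-prediction
  invariants intact.
* A per-sample Jaccard with empty truth and empty prediction counts as 1.
* Labels with a single class in the truth are skipped (with a warning) in
  AUC aggregation.

The **multi-label confusion matrix** (MLCM) is the piece that goes beyond
per-label counts: rows are true labels, columns predicted labels. A
correctly predicted label adds 1 to its diagonal cell; a *missed* true
label distributes one unit of weight equally across the sample's
false-positive labels, producing fractional off-diagonal entries. This
equal-split rule is the only simple allocation that reproduces the
fractional entries (0.5/2.5) of the reference worked example bundled with
the package. When a sample has no false positives the missed unit cannot
be placed in a 3×3 matrix; it is accumulated in an `unallocated` tally so
that `rowSums(raw) + unallocated` always equals the per-label true support
— making the dropped mass auditable rather than silent. Column-normalizing
the raw matrix gives the precision matrix, row-normalizing the recall
matrix; reports round to 2 decimals, internals keep full precision.

## Problem sizes in the test-suite and acceptance script

The unit and property tests run on deliberately small instances chosen to
exercise every code path at high statistical power per CPU-second: a
1–2 h single-patient noiseless night (25–50 events) for detector recovery;
a 40-patient cohort for the model plumbing; a 400-patient cohort with
15-minute recordings and 3 windows/patient (pool 4, batch 128, lr 2e-3,
up to 80 epochs) for the signal-recovery and ablation properties, where
the fused model's test macro AUC-ROC averages ≈ 0.70 over five seeds
against ≈ 0.57 for the signals-only baseline. The acceptance script runs
the same end-to-end computation on a 400-patient cohort with a single
seed-derived model.

## Known limitations

* The simulator's event waveforms are idealized; detector accuracy on real
  oximetry (sensor averaging, motion artifact bursts, Cheyne–Stokes
  patterns) will be lower than on synthetic ground truth.
* The cessation detector assumes a quasi-stationary breathing amplitude per
  patient after drift removal; strong position-dependent amplitude changes
  would call for a more local baseline.
* The CNN engine implements exactly the layers this architecture needs; it
  is not a general deep-learning framework, and CPU training time limits
  practical cohort sizes to a few thousand windows.
* Per-label decision thresholds are deliberately not tuned; threshold-free
  metrics (AUC-ROC/AUC-PR) are the primary yardstick under imbalance.
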