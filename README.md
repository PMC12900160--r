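# psgcomorb

Multi-label identification of obstructive sleep apnea (OSA) comorbidities —
arterial hypertension, diabetes mellitus, and asthma/COPD — from two
overnight polysomnography channels (pulse-oximetry SpO2 and nasal airflow
FP0) fused with routine clinical variables.

OSA patients frequently carry several of these diagnoses at once, and the
physiological traces of a sleep study plausibly encode all of them. The
package is aimed at sleep-medicine and biomedical-signal researchers who
want a complete, testable reference pipeline for that question:

* **Synthetic PSG cohort simulator** with exact ground truth: scheduled
  apnea–desaturation events with known markers t1/t2 (airflow cessation
  onset/offset) and t3/t4 (desaturation onset/recovery), clinical
  covariates, sensor artifacts, and a logistic label model that imprints
  comorbidity structure on both the clinical table and the signals.
* **I/O**: 16-bit EDF read/write, Feather columnar signal caches, canonical
  clinical/feature CSV tables.
* **Preprocessing**: resampling to 5 Hz, artifact repair (interpolation /
  masking / spike removal), zero-phase Butterworth + moving-average
  filtering, Savitzky–Golay derivative, fixed-length windowing.
* **Event engineering**: desaturation and cessation detection, causal
  one-to-one pairing, and the 11-column per-patient feature vector
  (Age, Gender, BMI, AHI, HeartRate, t3_t1_mean, t4_t2_mean,
  delta_t_FP0_mean, delta_t_SpO2_mean, mean_delta_SpO2, mean_slope).
* **Cohort statistics**: group means ± SD, one-sided Welch tests, absolute
  Cohen's d with the pooled standard deviation

  `d = |m1 − m0| / sqrt(((n0−1)s0² + (n1−1)s1²) / (n0+n1−2))`,

  and AHI-severity stratified slope summaries.
* **Multi-branch 1D-CNN**: three convolutional signal branches (SpO2,
  dSpO2/dt, FP0; conv → batch-norm → ReLU → dropout → global average
  pooling) plus a dense clinical branch, concatenated into a 3-unit sigmoid
  multi-label head; class-weighted binary cross-entropy
  (`w_j = (N − n_j)/n_j`) or focal loss; Adam with early stopping on
  validation macro AUC-PR. Implemented natively (vectorised R reference
  path + RcppArmadillo fused training step, verified identical).
* **Multi-label evaluation**: subset/flat/partial accuracy, Hamming loss
  (= 1 − flat accuracy), macro/micro/weighted F1, macro AUC-ROC / AUC-PR,
  demographic stratified error counts, and the fractional **multi-label
  confusion matrix** (MLCM): each missed true label distributes one unit of
  weight equally across the sample's false-positive labels; column- and
  row-normalization yield the precision and recall matrices.

## Worked example

```r
library(psgcomorb)

# a small synthetic cohort: 40 patients, 15-minute recordings
cfg <- cohort_config(
  n_patients = 40, duration = 0.25, sample_rate = 5,
  ahi_distribution = list(meanlog = log(18), sdlog = 0.5, lo = 0, hi = 25),
  seed = 21
)
coh <- generate_cohort(cfg)

# preprocess one patient and detect its events
pp <- preprocess_patient(coh$patients[[1]]$spo2, coh$patients[[1]]$fp0)
ev <- patient_events(pp, coh$patients[[1]]$clinical)
ev$features[, c("AHI", "delta_t_FP0_mean", "mean_delta_SpO2", "mean_slope")]
#>   AHI delta_t_FP0_mean mean_delta_SpO2 mean_slope
#> 1  24         59.06667        8.377764  0.1937676
```

This patient's six scheduled events had a true mean cessation duration of
63.8 s and mean depth 7.8 %; the detected values (59.1 s, 8.4 %) recover
them through the noise, and on noiseless configurations all four event
markers are recovered within 1 s.

The multi-label confusion matrix on the bundled reference label sets:

```r
print(build_mlcm(mlcm_example_labels()$truth, mlcm_example_labels()$pred))
#> Raw multi-label confusion matrix (rows = truth, cols = predicted):
#>     y1  y2 y3
#> y1 4.0 0.0  4
#> y2 0.0 3.0  0
#> y3 0.5 2.5  7
#> Class-wise precision: 0.89 0.55 0.64
#> Class-wise recall:    0.5 1 0.7
```

(labels in canonical order: y1 hypertension, y2 diabetes, y3 asthma/COPD)

The fractional 0.5/2.5 entries arise from a sample whose true asthma/COPD
label was missed while hypertension *and* diabetes were (wrongly)
predicted: the missed unit splits equally between the two false positives.

An end-to-end run (simulate → preprocess → features → stats → train →
evaluate) with manifests in every stage:

```r
run_pipeline("all", pipeline_config(seed = 1), out_dir = "run1")
```

or from a shell via the bundled CLI:

```sh
Rscript inst/cli/psgcomorb.R all --seed 1 --out run1
Rscript inst/cli/psgcomorb.R evaluate-fixture --out run1
```

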