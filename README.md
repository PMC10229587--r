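# shockadvice

Shockable-rhythm detection for automated external defibrillators (AEDs),
as an R package. An AED's shock advice algorithm (SAA) must decide from a
single ECG channel whether the current 8-second segment shows a shockable
rhythm — ventricular fibrillation (VF), rapid ventricular tachycardia
(VT) or ventricular flutter — and therefore whether a countershock should
be delivered. `shockadvice` implements a complete, testable SAA training
and deployment pipeline for researchers working on ECG arrhythmia
classification:

* **Synthetic cohorts** with patient structure (QRS pulse trains vs
  band-limited quasi-sinusoidal VF/VT), so every downstream stage runs
  without clinical data downloads.
* **Record ingestion** (native WFDB format-16 + rhythm annotations, or
  CSV), non-overlapping 8-s segmentation at 250 Hz, annotation-driven
  exclusions (noise, asystole, transitions, slow VT < 150 bpm, VF with
  peak-to-peak < 200 µV), and a three-stage filter chain (5-point moving
  average, 1 Hz high-pass, second-order 30 Hz Butterworth low-pass).
* **A 31-feature bank** of classical VF-detection statistics: temporal
  (TCSC, threshold-crossing and envelope counts, Count1–3, …), spectral
  (centroid, band powers, bandwidths, VF-filter leakage, wavelet
  correlation, …) and complexity measures (sample/fuzzy/dispersion/Rényi/
  wavelet entropy, Lempel–Ziv, phase-space box counting, …).
* **Feature ranking** by gradient-boosting split-improvement relevance

  $$R_n^2(\mathrm{Tr}) = \sum_i \hat s_i^2 I(v(i)=n), \qquad
    \hat s_i^2 = \tfrac{w_1 w_2}{w_1+w_2}(\bar y_1-\bar y_2)^2,$$

  averaged over trees, classes, patient-wise CV folds and repetitions
  (maximum scaled to 100), with recursive feature elimination producing
  strictly nested subsets of every size.
* **Component feature combinations (CFC)**: each subset is standardized
  on training statistics and rotated by the eigendecomposition of its
  correlation matrix, retaining all components (Σλ = n).
* **KNN classification** on component scores with patient-wise fivefold
  cross-validation, reporting accuracy, sensitivity, specificity and the
  balanced error rate BER = 1 − 0.5(Se + Sp).

## Worked example

```r
library(shockadvice)

# a 10-patient cohort, 30% shockable, low noise
coh <- generate_cohort(synth_cohort_spec(10, 10, shock_fraction = 0.3,
                                         noise_sd = 0.01, seed = 42))
fm <- extract_feature_matrix(coh)          # 100 x (3 + 31) feature table
cv <- repeated_cv(fm, FEATURE_NAMES, k = 15, n_reps = 5, seed = 42)
cv
#> <cv_result> 5-fold x 5 reps, K=15, 31 features
#>   Ac  100.00 +- 0.00
#>   Se  100.00 +- 0.00
#>   Sp  100.00 +- 0.00
#>   BER 0.00 +- 0.00
```

Every metric comes from folds whose test patients never appear in that
fold's training data, and the standardize→PCA→KNN stack is refitted
inside each training fold. On this high-SNR synthetic cohort the classes
are fully separable, hence 100% sensitivity and specificity with zero
spread; clinical data are harder — see the vignette for what the
synthetic cohorts do and do not emulate.

Metrics follow the usual conventions with shockable as the positive
class:

```r
compute_metrics(c(1,1,0,0,0,1), c(1,1,0,0,1,1))
#> Ac 83.33%  Se 75.00%  Sp 100.00%  BER 12.50%
balanced_error_rate(97.69, 99.71)   # BER from printed Se/Sp, in percent
#> [1] 1.3
```

Full training (RFE → per-size CV scoring → K grid search → deployable
model) and single-segment prediction:

```r
model <- train_pipeline(coh, saa_config(seed = 1))
predict_segment(model, generate_shockable(seed = 9)$samples)   # 1
save_model(model, "saa_model.json")                            # lossless
```

A thin command-line front end with verbs `simulate`, `segment`,
`features`, `train`, `evaluate` and `predict` is installed at
`system.file("cli", "saa.R", package = "shockadvice")`.

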