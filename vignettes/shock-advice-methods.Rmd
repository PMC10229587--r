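---
title: "Shockable-rhythm detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shockable-rhythm detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An automated external defibrillator (AED) must decide, every few seconds
and from a single ECG channel, whether the current rhythm is *shockable* —
ventricular fibrillation (VF), rapid ventricular tachycardia (VT) or
ventricular flutter — or *non-shockable* (sinus, paced, nodal rhythms,
atrial fibrillation, ectopy). A false negative withholds a life-saving
countershock; a false positive delivers one to a beating heart. The shock
advice algorithm (SAA) implemented here classifies non-overlapping 8-s
segments sampled at 250 Hz:

1. preprocess the segment (5-point moving average, 1 Hz high-pass,
   second-order 30 Hz Butterworth low-pass);
2. extract a bank of 31 temporal, spectral and complexity features, each
   the scalar output of a classical single-feature VF detector;
3. rank features by a gradient-boosting split-improvement relevance under
   patient-wise fivefold cross-validation and eliminate them recursively
   (RFE), giving nested subsets of every size;
4. standardize each candidate subset and rotate it into its *component
   feature combination* (CFC) — the full set of principal components of
   the training-fold correlation matrix;
5. classify with K-nearest neighbours on the component scores and report
   accuracy (Ac), sensitivity (Se), specificity (Sp) and the balanced
   error rate BER = 1 − 0.5(Se + Sp), all under repeated patient-wise
   fivefold cross-validation.

## The relevance model

For one regression tree, the relevance of feature $n$ is the sum of the
split improvements over the internal nodes that split on it,

$$R_n^2(\mathrm{Tr}) = \sum_i \hat s_i^2\, I(v(i) = n),\qquad
\hat s_i^2 = \frac{w_1 w_2}{w_1 + w_2}\,(\bar y_1 - \bar y_2)^2,$$

where $\bar y_{1,2}$ and $w_{1,2}$ are the weighted mean responses and
weight sums of the two daughter regions; $\hat s_i^2$ equals the reduction
in weighted squared error from fitting separate constants to the
daughters, and it is exactly the criterion our tree grower maximises, so
relevance conservation ($\sum_n R_n^2 = \sum_i \hat s_i^2$) holds by
construction. Trees are grown on the Newton pseudoresponses
$\bar y = \tfrac{K-1}{K}\,(y - p)/(p(1-p))$ with weights $w = p(1-p)$,
one tree per class and round, and class probabilities come from a softmax
over the two additive ensembles. The leading factor is $(K-1)/K$ with $K$
the number of classes (1/2 for this binary problem): the source
formulation of this gradient step uses the class count there, and we read
the published reuse of the tree-count symbol in that position as a
notational slip. Per-ensemble relevances are averaged over trees, the two
ensembles averaged, square roots taken, and the maximum scaled to 100 —
*after* averaging across folds and repetitions, since the alternative
(rescaling before averaging) is nowhere stated and rescaling last keeps
the averaged quantity an unbiased mean of the raw relevances.

Defaults: 100 trees per ensemble, depth 3, learning rate 0.1, minimum
leaf 5, probability clipping $\varepsilon = 10^{-6}$. RFE removes one
lowest-mean feature per round (ties: the alphabetically last of the tied
features, a deterministic convention), and the survival count (rounds
survived: 0 for the first removal, $n-1$ for the last survivor) is the
ranking statistic.

## The component feature combination

Features are standardized with training-fold means and standard
deviations, so the matrix eigendecomposed is the correlation matrix and
the eigenvalues sum to the feature count ($\sum_l \lambda_l = n$); all
$n$ components are retained, making the rotation invertible and
information-preserving. Sign indeterminacy is fixed by making each
loading column's largest-magnitude entry positive (first index on ties).
Standardization and rotation are refitted inside every training fold and
applied unchanged to the held-out fold — the published procedure implies
but never states the fit scope, and fitting per fold is the only choice
that cannot leak held-out information. Zero-variance columns get unit
standard deviation (with a warning) and surface as zero-variance
components rather than NaNs.

## The feature bank

The 31 feature names are fixed (MAva, bCP, TCSC, TCin, MEal, SEal,
Count1–3, CFre, A1, A2, PSan, CPow, Y_Li, bWT, bW, VFLM, HTra, CCal,
PSre, ACal, FCal, Kurt, CMea, DEnt, SEnt, Ener, REnt, FEnt, WEnt), but
the published table that introduces them does not define them; each is
implemented to a canonical reading from the VF-detection literature with
every tunable frozen in `feature_config()`:

* **TCSC** — per 3-s sub-window (1-s step), the percentage of samples
  above 0.2 of the sub-window peak, averaged. Amplitude-normalized.
* **TCin** — threshold-crossing *rate* (crossings of |x| through 0.2 of
  the 1-s-window peak, per second). A mean crossing interval would be
  *smaller* for fast disorganized rhythms, contradicting the published
  sign pattern this suite asserts (shockable mean greater), so the rate
  convention is used; the name is kept for table compatibility.
* **Count1–3** — percentages of samples above three amplitude tiers:
  half the peak, the mean absolute value, 0.2 of the peak.
* **MEal/SEal** — exponential-envelope refresh counts with 0.2 s and
  1.0 s time constants.
* **VFLM** — VF-filter leakage: the mean half-period is estimated from
  the mean absolute slope, the signal added to its half-period-shifted
  copy, and the residual normalized; near 0 for quasi-sinusoids.
* **Spectral group** — from the 0.5–30 Hz periodogram: centroid (CFre),
  low/mid band power fractions split at 5 and 10 Hz (A1/A2), first
  moment normalized by the dominant frequency (PSan), power within
  ±0.5 Hz of the peak (CPow), 10–90% inter-quantile width (bWT),
  spectral standard deviation (bW), order-2 Rényi spectral entropy
  (REnt), and a Mexican-hat wavelet self-similarity deficit between the
  segment halves (Y_Li, scale 0.1 s).
* **Complexity group** — Hilbert-plane and delay-plane (0.5 s delay)
  box-count fractions on a 40×40 grid (HTra, PSre), delay-plane
  trajectory length (ACal), binarized transition rate (FCal), windowed
  variance (CCal), excess kurtosis (Kurt), Lempel–Ziv complexity of the
  median-binarized signal (CMea), dispersion entropy (m = 2, 6 classes),
  sample and fuzzy entropy (m = 2, r = 0.2·SD, Chebyshev; fuzzy with
  Gaussian membership and template-mean removal), mean squared
  amplitude (Ener), and db4 wavelet entropy over 6 dyadic levels.

Degenerate inputs never produce NaN: the all-zero segment maps to a
documented constant vector (0 for amplitude and spectral features,
1/grid² for box fractions). Sample entropy is capped at log(2B) when no
(m+1)-template matches, and at the log of the pair count when no
m-template matches. Scale behaviour is part of the contract and is
tested: MAva and Ener scale with amplitude; TCSC, the Counts, the
entropies and the box fractions are invariant under positive rescaling.

## The synthetic cohorts

The generator exists so that every stage is testable without downloading
clinical databases. Non-shockable segments are periodic trains of
biphasic Gaussian-derivative pulses (σ = 15 ms, ≈100 ms support) at
40–140 bpm near the isoelectric line, with Gaussian noise and < 0.5 Hz
baseline wander. VF is an amplitude- and frequency-modulated
quasi-sinusoid: the dominant frequency follows a mean-reverting AR(1)
walk reflected at ±1.5 Hz around its nominal value per 1-s block, the
amplitude walks within ±30%, a second harmonic with drifting phase adds
disorganization, and a 4th-order 10 Hz low-pass enforces the 0–10 Hz
shockable bandwidth by construction. VT is a near-monomorphic skewed
sinusoid whose rate is its dominant frequency × 60. `amplitude_mv` is
the clean-waveform peak-to-peak amplitude, so the 200 µV exclusion rule
is directly exercisable. Cohort defaults (250 Hz, 8 s, 18% shockable
prevalence, 0.05 mV noise) mirror the corpus the method was published
on; per-patient waveform parameters are drawn once per patient so
patient-wise cross-validation is meaningful.

What the generator does *not* emulate: electrode artefacts, muscle
noise, paced rhythms, atrial fibrillation, rhythm transitions inside a
window, or the amplitude statistics of real coarse/fine VF. Passing the
synthetic end-to-end checks therefore demonstrates that the machinery is
correct and leak-free, not that the clinical operating point is
reproduced; the published corpus metrics require the clinical databases
and are out of scope here.

## Evaluation protocol and numerical choices

Folds are patient-disjoint: patients are shuffled and dealt round-robin,
so fold sizes differ by at most one patient. Within a repetition, fold
predictions are pooled before metrics are computed (per-fold averaging is
available via `pool = FALSE`); the published text does not say which was
used, and pooling weights every segment equally. KNN uses Euclidean
distance and unweighted votes with exact ties broken toward
non-shockable (the conservative choice for a device that shocks on 1).
K is selected by CV accuracy over a grid (default 5–100), smallest K on
ties. Record-level 70/30 splits round the training count.

Problem sizes used by the tests and the acceptance script, chosen once:
informative-feature recovery uses 100 seeded runs of n = 500 with 1
informative (shift 2 SD) among 10 features at the default boosting
settings; RFE recovery uses 100 runs of n = 300 with 3 informative
features (shift 1.5 SD) among 8, with a lighter 30-tree depth-2 boosting
configuration inside the CV loop; the end-to-end check trains the full
pipeline on a 20-patient × 20-segment high-SNR cohort (0.01 mV noise)
and expects Se = Sp = 100%, with monotone degradation at 1.5 and 4 mV
noise. The degradation levels are far apart deliberately: accuracy is a
step-like function of noise on small cohorts, and adjacent levels would
test sampling jitter rather than the trend.

## Known limitations

* The feature definitions are canonical readings, not bit-reproductions
  of the original implementations the published table drew on; Table-2
  magnitudes are not reproduced (its scaling is unexplained), only the
  sign pattern of the class means is asserted.
* The WFDB support is the minimal native subset needed here (format-16
  signals, rhythm annotations); obscure header variants are rejected
  rather than guessed.
* The published corpus totals (1135/5185 segments) depend on an
  unstated mixed-window labeling rule and are not reproducible without
  the original databases; segment labeling here uses the
  majority-covering rhythm with transition windows flagged and excluded.
* `bCP` appears with contradictory directions in the published table
  and its surrounding discussion; the implementation follows the
  discussion (steep QRS slopes give large bCP) and the direction suite
  does not assert it.
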