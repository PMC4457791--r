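---
title: "Serum peptidome classification: models, parameters and design choices"
author: "pepClassify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum peptidome classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models behind
each stage, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## The analysis in one paragraph

A serum peptidome profile is a low-resolution linear-mode MALDI-TOF spectrum
of circulating peptides recorded over 800–10,000 Da. Cohorts of such spectra
are preprocessed into a samples × peak-areas matrix; peaks whose areas differ
between patients with TKI-sensitive *EGFR* mutations and wild-type patients
are identified; a classifier built on a small peak panel labels new patients
"mutant", "wild" or "unclassifiable"; and the labels are evaluated against
the tissue assay (concordance) and against clinical outcome under EGFR-TKI
therapy (response rates, progression-free and overall survival).

## Preprocessing model

Each stage operates on a `MassSpectrum` (strictly increasing m/z grid in Da,
finite intensities) and the chain is strictly deterministic.

**TIC normalization** (`normalizeTIC`). Intensities are scaled so the
trapezoidal integral equals `targetTic` (default 1). This makes all
downstream areas *normalized-TIC units*: only ratios and ranks are
meaningful, absolute values are not comparable across instruments. The
operation is idempotent and refuses an all-zero spectrum.

**Recalibration** (`recalibrateSpectra`). Real spectra carry a small
per-acquisition affine m/z distortion. Prominent apexes are detected per
spectrum (lightly pre-smoothed, local-baseline-corrected, SNR ≥ 5, top 60 by
height, parabolic apex interpolation for sub-grid precision), pooled and
clustered with a mass-dependent tolerance of max(0.3% m/z, one grid step).
Clusters present in ≥ 80% of spectra become calibration points; each
spectrum's axis is mapped onto the cluster consensus (or onto known
`reference` masses when supplied) by least squares with one
outlier-trimming pass — a single mismatched calibration point otherwise
tilts the whole axis — and resampled onto its original grid. Collections
with fewer than two common peaks, or spectra with fewer than two matches,
pass through unwarped and flagged.

**Smoothing** (`smoothSpectrum`). Savitzky–Golay, polynomial order 3,
default window 2 Da. With the resolution model below, the narrowest peaks
(σ ≈ 0.45 Da near 1,365 Da) have FWHM ≈ 1 Da; a substantially wider window
would flatten them, while 2 Da still gives the expected noise averaging for
the 0.25-Da default grid. `order = 0` degenerates to a moving average.

**Top-hat baseline subtraction** (`subtractBaselineTophat`). The baseline
estimate is the morphological opening — erosion then dilation with a flat
structuring element — whose length is 10% of the analyzed mass range
("minimum baseline width"), implemented as O(n) monotonic-deque rolling
extrema with windows that shrink at the boundaries (the opening stays
idempotent under this convention). On noisy signals the opening tracks the
*lower noise envelope*, leaving a small positive stochastic floor
(≈ +3 σ of the smoothed noise) between peaks; left in place, that floor
inflates every SNR and defeats both detection and per-spectrum quality
control. The default `zeroLevelWindow = 30` Da therefore subtracts a rolling
median of the residual — windows wide enough that no peak (σ ≤ 3.3 Da)
shifts its median — after which the signal fluctuates symmetrically around
zero between peaks. Integration later clips at the zero level.

**Noise** (`estimateNoise`). Windowed median absolute deviation × 1.4826
(Gaussian-consistent), 300-Da windows, linearly interpolated to each grid
point. Robust to sparse tall peaks by construction.

**Peak detection** (`detectPeaks`). Run once per cohort on the mean of all
preprocessed spectra (a common peak list for every sample). The spectrum is
segmented at local minima; a segment becomes a peak when its apex SNR
reaches 5. Adjacent detected segments whose shared valley exceeds 75% of the
lower apex are merged (a noise-split maximum); bounds are the flanking
minima tightened to zero-crossings; the centroid is the intensity-weighted
mean within bounds. Bounds are pairwise non-overlapping by construction.

**Integration** (`integrateAreas`). Zero-level trapezoidal integral between
the consensus bounds, clipped at zero. Before integrating, the window may be
re-centred on the spectrum's own apex within ±0.3% m/z, absorbing residual
calibration error. Bounds are treated as closed intervals for integration so
that abutting definitions sum exactly to the undivided integral.

**Spectrum quality** (`buildFeatureMatrix`). A spectrum is *invalid* when
fewer than 50% of the consensus peaks reach a local SNR of 2 in that
spectrum. Invalid samples keep their column with all-missing areas and are
excluded listwise from statistics and training; a classifier returns
"unclassifiable" for them. The rule is a package choice: some spectra in any
real cohort fail quality control, and the generator reproduces such spectra
by collapsing peak amplitudes (×0.02) below the detection SNR.

## Differential peaks

`differentialPeaks` reports, per consensus peak, the class-conditional
mean ± SD, Welch's *t* (primary ranking statistic), the Wilcoxon rank-sum
test, and Benjamini–Hochberg adjusted values for both. The significance
*call* uses the raw Welch p at α = 0.05 — the historical selection rule this
workflow mirrors — while the BH columns are reported for modern reuse. With
mean ± SD reporting and heavy-tailed peak areas, Welch and rank-sum can
disagree; both are always computed.

## Classifiers

All classifiers operate on per-peak z-scores from training statistics, so
classification is invariant to per-peak affine rescaling of the inputs.

* **Quick classifier** (`trainQC`): peaks ranked by Welch p, top 25 kept;
  each peak votes for the class with the nearer standardized mean, with
  weight −log₁₀ p; the weighted vote decides. Ties go to "wild".
* **Prototype network** (`trainSNN`): LVQ1 with 3 prototypes per class,
  initialized at the class means plus seeded jitter; the nearest prototype
  is attracted to same-class samples and repelled otherwise, learning rate
  decaying linearly from 0.3 over 40 epochs. Per-class covariance traces are
  stored as width heuristics. Classification is nearest-prototype.
* **GA-kNN** (`trainGAKNN`): a genetic algorithm searches peak subsets of
  size 3–8. Chromosomes are index sets; crossover (rate 0.7) draws the child
  from the union of its parents; mutation replaces each slot with
  probability 0.05 by a random non-member peak; one elite is carried
  unchanged, so the elite fitness trace is non-decreasing. Fitness is the
  stratified 5-fold cross-validated accuracy of k-NN (k ∈ {3, 5, 7},
  Euclidean on z-scores) on the candidate subset, with fold assignments
  fixed per run and fitness values cached. Population 64, 40 generations.
  Vote ties (possible only for even k) break toward "wild" — the
  conservative direction, against recommending TKI.

**Cross-validation** (`crossValidate`): ten independent stratified random
splits each leaving out 20% per class; `crossValidationPct` is the mean
holdout accuracy and `recognitionPct` the resubstitution accuracy of the
final refit. Unstratified splitting is refused (a class could vanish from a
holdout). For GA-kNNs the reported CVResult fixes the selected subset and
refits only the k-NN exemplars per split — the convention of the commercial
software this mirrors. Because subset selection saw all training samples,
that estimate retains selection optimism; the GA's *internal* 5-fold
estimate is never reported for this reason, and an unbiased protocol would
re-run the GA inside every split at ~10× cost.

**Persistence** (`saveModel`/`loadModel`): JSON at 17 significant digits
(exact double round-trip) with a format version and an md5 payload checksum;
truncated or edited files fail to load.

## The synthetic-data generator

`simulationConfig()` defaults define the study conditions: 50 + 50 training
patients, spectra on a 0.25-Da grid over 800–10,000 Da; ten
class-discriminating peaks whose areas are drawn from zero-truncated normals
with the calibrated class-conditional means and SDs (the published
differential-peak table; only mean ± SD is published, so the family is a
modelling choice); 120 background peaks at fixed catalogue positions
(deterministic internal seed, ≥ 15 Da from any discriminating peak,
log-normal mean areas); Gaussian peak shapes with σ = m/3,000 (linear-mode
TOF-like resolution — no widths are published); a decaying-exponential
baseline (amplitude 20, decay constant 1,500 Da, offset 1 — standard MALDI
low-mass background, none is published); iid intensity noise σ = 0.5 raw
units; a log-normal per-spectrum intensity factor (sdlog 0.15) emulating
total-ion-current spread; a per-spectrum affine m/z distortion (|scale−1| ≤
3×10⁻⁴, |offset| ≤ 0.5 Da); and a 2.4% rate of low-quality spectra
(all peak amplitudes × 0.02, collapsing the signal below SNR 5 — the
mechanism behind unclassifiable samples is not published, so suppressed
amplitude is our model of it). The peak at m/z 4438.43 appears in the
published classifier but not in the differential table; it is simulated as
weakly informative, class means 0.5 pooled SD apart — it must carry some
signal to have been selected, but no published effect size exists.

Outcomes (`outcomeParams()`): RECIST response drawn per patient from the
true class's objective-response (0.596 / 0.088) and disease-control
(0.872 / 0.353) probabilities — complete response has probability zero, its
observed count being zero — and exponential PFS/OS with medians 10.0 / 2.3
and 29.0 / 28.0 months, right-censored at a 40-month horizon (the maximum
reported follow-up). One study seed spawns per-patient substreams, so any
single patient is reproducible in isolation.

**What the generator does not emulate** — and hence what passing tests do
and do not show: isotope envelopes and adducts, correlated peak areas
(biological co-regulation), mass-dependent or multiplicative noise, detector
saturation, batch drift, and non-normal area distributions. Peak areas are
conditionally independent given class, which makes the simulated
classification task *easier* than the real one: the synthetic GA-kNN
reaches ~95–98% cross-validation where the published classifier reached
81.23%. Tests on synthetic cohorts therefore validate the pipeline's
correctness (recovery of planted structure, calibration of its statistics),
not its expected accuracy on real serum spectra.

## Numerical choices and degenerate inputs

* Rolling extrema shrink their windows at the signal boundaries; the opening
  remains idempotent under this convention and is tested against a
  brute-force sliding-min/max oracle.
* Intervals are closed-left/open-right in Da for assignment semantics, but
  integration includes both endpoints so abutting areas are additive.
* The KM median is the *earliest* time with S(t) ≤ 0.5 ("not reached" if the
  curve never crosses), not the midpoint of an exactly-0.5 plateau; the
  median CI uses the log(−log) transform. The large-sample κ test uses the
  Fleiss null variance; degenerate margins (pₑ = 1) yield a flagged NA.
* Sensitivity, specificity and accuracy count unclassifiable spectra in
  their denominators (the only convention that reconciles the published
  percentages with the published counts); κ excludes them.
* χ² association tests use no continuity correction; Fisher's exact test is
  reported alongside.
* All-zero spectra cannot be normalized and surface as errors (single
  spectra) or invalid samples (cohorts); a cohort whose spectra are all
  invalid is an error.

## Problem sizes in the shipped tests

The suite exercises full 50 + 50 cohorts at the default grid for the
parameter-recovery checks (20 seeds), and reduced ranges or tiny grids where
only plumbing properties (determinism, order-invariance, round-trips) are at
stake. These sizes are the package's own desk-scale choices; every
distributional assertion states its tolerance via the corresponding
binomial or large-sample band.

## Known limitations

Single-charge linear-mode assumption throughout; no isotope deconvolution or
batch normalization; two-class problems only; the GA's reported
cross-validation retains subset-selection optimism (see above); and absolute
peak areas are in normalized-TIC units, not comparable to areas from other
software.
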