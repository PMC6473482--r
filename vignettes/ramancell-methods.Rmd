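---
title: "Methods: simulation and chemometrics of live single-cell Raman spectra"
author: "ramancell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and chemometrics of live single-cell Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`ramancell` implements a complete analysis chain for label-free live
single-cell Raman spectroscopy of cancer cell lines: a synthetic-spectrum
generator that emulates a two-window confocal acquisition of five cell lines
(SW480, SW620, HL60, HT29, HCT116), the standard preprocessing chain for such
data, Gaussian band decomposition, filtered band correlation analysis, a
cross-validated classifier suite, and partial least squares regression of the
colorectal adenocarcinoma lines against ordinal Duke stage. This vignette
explains the models behind each stage, the parameters that matter, and the
design decisions taken where the design was genuinely open.

## 1. The synthetic-data generator

No public single-cell Raman dataset exists for this panel of cell lines, so
the package ships a generator whose draws have the statistical structure the
downstream analysis assumes. One simulated cell consists of two acquisition
windows (300–1800 and 1800–3200 cm⁻¹, 1 cm⁻¹ channels, sharing the single
channel at 1800 cm⁻¹) containing:

* **Cellular bands.** A catalogue of 29 Gaussian bands
  (`band_catalogue()`) spanning the fingerprint and CH-stretch regions, with
  biochemical assignments (nucleic-acid ring breathing at 782 cm⁻¹,
  phenylalanine at 1004 cm⁻¹, the Amide III secondary-structure sub-bands,
  the cytochrome c resonance series at 748/1128/1310/1585 cm⁻¹, the
  CH₂/CH₃ stretches, …). Mean amplitudes are expressed relative to the
  Amide I α-helix band (= 1).
* **Per-line amplitude multipliers.** Each cell line scales every band by a
  calibrated multiplier encoding the qualitative between-line differences
  reported for these lines: the nucleic-acid ordering
  HL60 > HCT116 > SW620 > HT29 > SW480 at 782/810 cm⁻¹; a higher CH₂:CH₃
  ratio for SW620 with higher overall CH-stretch intensity for SW480; more
  disordered Amide III structure for SW480 and more β-sheet for SW620;
  lactate (1725 cm⁻¹) rising and CH-stretch above 2900 cm⁻¹ falling with
  adenocarcinoma stage; and a reduced cytochrome c series for HCT116. The
  multipliers are versioned constants (`line_multipliers()`), calibrated
  once so that the default datasets reach the reference classification
  accuracies while no single band dominates the class separation (the
  published method ordering PCA/LDA ≥ boosted trees ≥ single tree only
  emerges when the discriminative signal is spread over many moderate
  bands).
* **Cell-to-cell variability.** Band amplitudes fluctuate log-normally per
  cell (CV 0.15 per band; 0.05 for the Amide I reference bands, which also
  stabilizes the normalization), with one shared latent factor (sd 0.2) per
  covariance group (cytochrome c, nucleic acid, lipid series) so that
  group members co-fluctuate with pairwise correlations well above the 0.3
  reporting threshold while unrelated bands stay below it. A global
  log-normal intensity factor (sd 0.25) models focus/size variation; the
  per-class spectral variance magnitudes are not published, so these widths
  are realistic choices fixed once, not fitted quantities.
* **Instrument artefacts.** A smooth fluorescence baseline (cubic in the
  normalized wavenumber, per-cell log-normal height), the broad quartz
  substrate band at 480 cm⁻¹ scaled by a per-cell mixing coefficient
  *a* ~ logN(log 1.1, 0.15) (the quantity background subtraction must
  recover), additive Gaussian detector noise (sd 6 counts against an
  Amide I level of ~1200 counts), Poisson cosmic-ray spikes (rate 1 per
  window, single-channel, 10–50× the local signal), and a per-experiment
  wavenumber mis-calibration (sd 1.2 cm⁻¹, truncated at ±4) shared by all
  spectra of that experiment.
* **Study structure.** The default per-class counts are the study's
  (167 SW620, 163 SW480, 89 HL60, 190 HT29, 71 HCT116; 680 cells), split
  into experiments of at most 85 cells, each with five cell-free background
  spectra and one silicon calibration spectrum.

What the generator deliberately does **not** model: confocal depth response,
photobleaching kinetics, cell-morphology effects, detector nonlinearity, or
Lorentzian/Voigt line shapes (the decomposition stage fits Gaussians, so the
generator draws Gaussians). Passing tests therefore demonstrate the
correctness and calibration of the *pipeline*, not the biology of real
cells; the real-data PC variance percentages or absolute band intensities
are out of reach by construction, and only qualitative orderings are
reproduced.

## 2. Preprocessing chain

`preprocess_dataset()` applies, in a fixed recorded order per cell:

1. **Despiking.** Modified z-score of the second differences, threshold 8.
   A channel is flagged only when its second difference also dominates its
   neighbours' (≥ 1.5×): a cosmic spike is a one-channel event with a
   (+A, −2A, +A) second-difference signature, whereas smooth band curvature
   changes slowly — this keeps noiseless band apexes untouched and flags
   exactly the spike channel, which is replaced by the local median.
2. **Silicon wavenumber calibration.** The apparent silicon line position is
   located by 3-point parabolic interpolation of the maximum; the axis is
   shifted by (520.5 − apparent position), the same shift for both windows
   of every cell of the experiment.
3. **Zero offset.** Vertical translation so the minimum intensity is zero.
4. **Scaled background subtraction.** The per-experiment mean cell-free
   background is scaled by the least-squares coefficient *a* fitted on the
   quartz window (430–530 cm⁻¹, configurable) and subtracted from both
   windows. *a* is reported per cell; on default synthetic data it recovers
   the generator's mixing coefficient with r > 0.99 and MAE below 5%.
5. **Savitzky–Golay smoothing**, window 11 points, order 3 (exact on cubic
   signal, < 1% attenuation of a σ = 15 cm⁻¹ band at 1 cm⁻¹ sampling).
6. **Window stitching** at 1800 cm⁻¹: window 2 is shifted to match the mean
   intensity on the shared channels, which are then averaged; abutting
   windows are concatenated. The stitched spectrum is resampled onto the
   integer wavenumber grid so that all experiments (whose calibrated axes
   differ by fractional shifts) share one analysis grid.
7. **Truncation** to [730, 3100] cm⁻¹ (closed endpoints).
8. **Baseline correction** by iterative asymmetric penalized least squares:
   minimize Σ wᵢ(yᵢ−zᵢ)² + λ Σ(Δ²zᵢ)² with wᵢ = p for yᵢ > zᵢ and 1−p
   otherwise; p = 0.01, λ = 1e7, at most 50 reweighting iterations with a
   1e-6 weight-convergence criterion. λ was set by truth recovery on
   simulated baselines: at λ = 1e5 the penalty length (~λ^¼ ≈ 18 channels)
   is comparable to the σ ≈ 16 cm⁻¹ Amide I/CH bands, so the baseline
   creeps up under them (6% RMS error on band-free channels, ~7% band
   attenuation); λ = 1e7 recovers the truth to ~1% RMS with < 1%
   attenuation while remaining flexible enough for any smooth fluorescence
   background. Both parameters are exposed.
9. **Excision** of the silent region (1750, 2800) cm⁻¹ (open interval,
   recorded in the excision mask).
10. **Amide I normalization** (band-analysis branch): division by the
    maximum of the smoothed intensity on 1600–1690 cm⁻¹ — a peak height,
    not a fitted area, chosen for robustness and order-independence; the
    maximum becomes exactly 1.
11. **Chemometrics branch:** additionally truncated at 3000 cm⁻¹ and
    standardized per spectrum by SNV (mean 0, sd 1). SNV is applied per
    spectrum, the conventional reading of "standard normal variate".

A cell failing any stage is skipped with a logged reason; the dataset
proceeds. Re-running the chain on identical inputs is bit-identical.

## 3. Band analysis

Class mean ± sd spectra are channelwise moments of the normalized matrix.
Gaussian decomposition (`fit_region()`) is Levenberg–Marquardt nonlinear
least squares with nonnegative amplitudes; with several class means and
`shared = TRUE`, peak centers and widths are global parameters and only the
amplitudes are per class (the convention for comparing secondary-structure
content across lines). Default regions: Amide III 1200–1320 cm⁻¹ with four
sub-bands (β-sheet 1240, disordered 1254, α+β 1272, α-helix 1296 — the
catalogue's initial values; the literature gives the labels but not exact
centers, so these are exposed in the region spec), Amide I 1600–1700 cm⁻¹,
CH-stretch 2800–3100 cm⁻¹ with five peaks. The cytochrome c line at
1310 cm⁻¹ lies inside the Amide III window; a four-Gaussian decomposition
absorbs it into the α-helix band, which is why the fit is initialized with
four peaks only, mirroring practice.

Correlation analysis computes Pearson r for every retained wavenumber pair
with p-values from the t-transform (no multiple-testing correction — the
analysis uses a raw p cut of 1e-4), zeroes entries with p > 1e-4, and
reports pairs with |r| > 0.3 sorted by |r|. Constant columns get r = 0 and
are flagged.

## 4. Classifier suite and evaluation protocol

* **PCA** (mean-centered, 25 components by default) with a fixed sign
  convention (largest-|weight| element positive).
* **LDA**: one-vs-one Fisher discriminants on the PC scores with pooled,
  ridge-regularized (1e-6) within-class covariance; k classes give
  C(k, 2) pairwise discriminants (10 for five classes) combined by majority
  vote, ties broken by the largest summed projection margin.
* **Single tree**: CART-style Gini tree on the raw wavenumber intensities
  (not PC scores), with the split wavenumbers reported.
* **Boosted small-tree ensemble**: SAMME boosting of depth-≤2 Gini trees
  (20 rounds by default) with a per-wavenumber selection-frequency table.
  This is a deliberate stand-in for a C5.0-style ensemble, whose exact
  algorithm is proprietary in detail; what the analysis uses — many small
  trees plus the frequency of chosen wavenumbers — is preserved. When a
  round fits its training sample perfectly there is nothing left to
  upweight, so boosting restarts from a bootstrap-perturbed weight vector
  instead of stopping; this keeps exploring alternative split wavenumbers
  and is what makes the ensemble more accurate than a single tree on
  separable data.
* **Linear SVM**: soft-margin, C = 1, one-vs-one for k > 2. Other kernels
  are deliberately not offered.

**Cross-validation** is stratified 10-fold with 5 repetitions (folds
re-randomized each repetition); stratification prevents empty-class folds at
the smallest class size (71). Every data-dependent fitting step — PCA
included — is nested inside the training folds; SNV is per-spectrum and
therefore leakage-free by construction. The accuracy standard error is
σ/√N over the N = 50 fold estimates. A deliberately leaky variant
(whole-data PCA) is exercised in the tests against the nested protocol on
label-permuted data. The learning curve resamples class-balanced training
subsets with a 50-cell test draw and fits a saturating Weibull sigmoid
a·(1 − exp(−(n/λ)^κ)) with a ≤ 100; a flat curve leaves the sigmoid
unidentified, in which case the plateau mean is reported as the saturation.

## 5. Stage-trend PLSR

The adenocarcinoma lines are coded SW480 = 1 (Duke B primary), HT29 = 2
(Duke C primary), SW620 = 3 (Duke C lymph-node metastasis) and regressed by
SIMPLS partial least squares. Components are sign-oriented so scores
increase with the stage code. A component is *selected* only when unpaired
one-tailed two-sample t-tests show its mean score strictly increasing across
both adjacent stage pairs at p < α = 0.01 (the direction "significant
increase with stage" fixes the one-tailed reading); requiring both adjacent
pairs makes the 1-vs-3 comparison implied, and an all-pairs variant is
available via `pairs = "all"`. Under the stage-null both tests must pass by
chance, so the false-selection rate is ~α² per component — comfortably below
α, which the tests verify by simulation.

The PLSR input is the Amide-I-normalized branch rather than the SNV branch:
SNV re-standardizes each spectrum by its own mean and sd, which cancels the
stage-wise CH₂ contrast at 2850 cm⁻¹ that the analysis is designed to
expose; on the normalized branch the selected component-1 weights are
positive at the lactate carbonyl (1725 cm⁻¹) and negative in the CH-stretch
region, matching the biochemical reading.

## 6. Numerical choices and degenerate inputs

* Truncation/excision intervals are closed at their stated endpoints;
  (1750, 2800) is open, so 1750 and 2800 themselves are retained.
* Parabolic peak interpolation returns the grid maximum when the
  three-point curvature vanishes; silicon calibration errors out when no
  peak is detectable above the noise floor.
* SNV errors on zero-variance spectra; Amide I normalization errors on a
  non-positive maximum; background fitting errors when the quartz window
  lies outside the spectrum.
* The despiking MAD statistic being zero (constant spectra) means no
  spikes.
* Band fits bound centers to ±15 cm⁻¹ of their initial values and widths to
  [0.5, 80] cm⁻¹, and report non-convergence as an error with the residual.
* All stochastic steps take explicit seeds; identical configuration + seed
  is bit-identical, and the RNG state is restored after seeded calls.

## 7. Problem sizes used by the packaged checks

The acceptance script reproduces the headline accuracies at full study size
(330 and 680 cells, 10-fold × 5 CV). The unit/property tests run the same
code paths on reduced datasets (40–80 cells per class, 2 repetitions, 600
null replicates for the selection-rate check) — sizes chosen so each
property has comfortable statistical power while the suite stays quick.

## 8. Known limitations

* Calibration constants target qualitative orderings and headline
  accuracies, not absolute intensities of real cells.
* The ensemble is an open re-implementation of "many small boosted trees",
  not the C5.0 release; split choices can differ from Quinlan's algorithm.
* The baseline algorithm is asymmetric penalized least squares, not the
  exact published variant the original preprocessing cited; acceptance is
  truth-recovery on synthetic baselines.
* One-vs-one LDA margins are combined by simple voting; calibrated
  posterior probabilities are not provided.
* Only Renishaw-style two-column text exports are read; no binary `.wdf`
  support, no 2D Raman mapping.
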