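---
title: "Methods: tissue-type differential metabolomics for MALDI MSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-type differential metabolomics for MALDI MSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msidiff)
```

## The problem

MALDI-TOF mass spectrometry imaging (MSI) records one mass spectrum per
tissue pixel, typically at a spatial resolution of tens of micrometres. In
oncology applications each pixel additionally carries a histology label
(here: non-cancer epithelium `NCE`, `stroma`, `cancer`, or chemical-
`matrix`-only background), and the scientific question is which metabolite
and lipid masses differ between tissue types across a cohort of patients.

Two properties of such data shape the statistics:

* **Hierarchy.** Pixels are nested in tissue sections, which are nested in
  patients. Thousands of pixels from one patient are not thousands of
  independent observations.
* **Spatial autocorrelation.** Neighbouring pixels share both biology and
  acquisition artefacts; residuals are correlated over a length scale of
  several pixels.

msidiff implements an analysis chain that deals with both: spectral
preprocessing down to a peak-height matrix, pairwise OPLS-DA with
leave-one-patient-out cross-validation and permutation testing, and a
fraction-based iterative linear mixed model for univariate testing.

## Preprocessing model

Spectra are read from imzML (continuous mode natively; processed mode is
resampled onto a common axis by linear interpolation with bin width equal to
the median native spacing). The chain is:

1. **Recalibration** (optional): calibrant masses are located as local
   maxima within a ppm tolerance, apexes are refined by 3-point parabolic
   interpolation, and a polynomial of mass error versus m/z (cubic with four
   or more anchors, else degree `matches - 1`) is subtracted from the axis.
2. **TIC normalization**: each spectrum is divided by its total ion count.
   Normalization precedes mean-spectrum computation; the order is fixed
   here because averaging unnormalized spectra would weight pixels by their
   overall signal yield.
3. **Mean spectra** per tissue label, across patients.
4. **Baseline correction** of the mean spectra with the familiar
   (precision, relative offset) parameterization: the axis is split into
   `precision` equal segments, each contributing an anchor at
   `segment minimum + relative_offset/100 * (1.4826 * MAD)`; the baseline is
   the linear interpolation through the anchors. This is a documented
   reinterpretation of those desktop-software controls; the defaults
   (20, 25) keep their conventional values.
5. **Matrix subtraction**: the matrix-only mean spectrum is subtracted from
   each tissue mean, clipped at zero, removing chemical background peaks.
6. **Peak selection** on each subtracted mean spectrum: local maxima with a
   minimum signal-to-noise ratio of 2 (noise is a 501-point windowed
   `1.4826 * MAD`, a robust estimate chosen because peak-selection noise
   models differ between tools) and an absolute threshold of 0.25
   (positive mode) or 0.2 (negative mode). Mean spectra are rescaled to
   base peak = 100 before thresholding, so the absolute thresholds are in
   percent-of-base-peak units: TIC-normalized spectra sum to 1, so a fixed
   threshold can only be meaningful on a declared intensity scale, and
   percent-of-base-peak is the convention those constants come from.
7. **Deisotoping**: peaks within 50 ppm of `parent + k * 1.00335` Da
   (k = 1..3) of a more intense, lower-mass peak are removed; an optional
   exclusion list removes known lipid fragments.
8. **Merging**: the per-tissue lists are pooled and single-linkage
   clustered at the extraction window width; each cluster is represented by
   its intensity-weighted mean m/z, which guarantees the minimum-spacing
   invariant that extraction windows never overlap.
9. **Extraction**: for every annotated non-matrix spectrum, the highest
   data point within a total window of 150 ppm (positive) or 200 ppm
   (negative) centred on each peak gives the peak-height matrix. The window
   is interpreted as a *total* width; it absorbs the per-spectrum mass
   shifts that survive recalibration.

## Multivariate model

Analyses run on auto-scaled data (columnwise mean 0, unit sample SD;
zero-variance columns are dropped and the scaling parameters are stored so
held-out rows are scaled with training-set parameters only). PCA is
provided for structure inspection.

OPLS-DA removes class-orthogonal variation before fitting a single
predictive PLS component. With classes encoded +1/−1, each orthogonal round
computes `w ∝ X'y`, `t = Xw`, `p = X't/(t't)`,
`w_o ∝ p − (w'p)w`, and deflates `X` by the orthogonal component
`t_o p_o'`; the predictive component is then fitted on the filtered matrix.
`n_orth` defaults to 1 — the filtered model reports one predictive latent
variable per comparison, and one orthogonal round suffices for that
presentation; the realized count is recorded when extraction stops early.
With `n_orth = 0` the model is exactly one-component PLS-DA, which the
tests exploit as an algebraic identity.

Classification uses the midpoint of the class mean scores as threshold,
with ties deterministically assigned to the positive class. Validation is
leave-one-patient-out: all spectra of one patient form the held-out fold,
and the model (including scaling) is refitted per fold. Significance comes
from permutation testing: class labels are permuted uniformly over spectra
and the cross-validated accuracy recomputed, with
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`. Permuting spectrum labels
ignores the spatial autocorrelation of pixels, which makes the permutation
test generous for per-pixel classes; the iterative mixed model below is the
analysis' answer to autocorrelation, not the permutation test.

Variable importance on the projection is computed on the single predictive
component: `VIP_j = sqrt(K) |w_j| / ||w||`, so `sum(VIP^2) = K` exactly;
VIP ≥ 1 is the conventional importance cut. Total-VIP variants over
multiple components exist, but with one predictive component both reduce to
the same quantity up to the orthogonal-variation share, and the per-mass
VIP-versus-loading plot expects one VIP per mass.

## Univariate model

For each mass and tissue pair, the model is

`height = b0 + b1 * tissue + u_patient + e`,  `u ~ N(0, σu²)`, `e ~ N(0, σe²)`

fitted by REML, with the patient intercept as the only random effect —
patient is the only grouping variable in the design. The fit profiles the
variance ratio `σu²/σe²` and solves the generalized least squares problem
in closed form at each evaluation of a one-dimensional optimizer. This
makes a fit cost microseconds, which the iterative scheme needs; the
implementation is validated against `nlme::lme` (coefficient, standard
error and variance components to four significant digits) in the test
suite. Wald p values use a normal reference; REML degrees-of-freedom
conventions differ across tools, and with the subsample sizes used here the
normal reference is the transparent choice (it is slightly liberal per
iteration; averaging adjusted p values over iterations is strongly
conservative, and the realized type-I rate is checked by simulation).

The iterative procedure draws a simple random sample of 0.5% of the spectra
of the two compared tissues per iteration (minimizing the chance that
neighbouring, spatially correlated pixels enter the same model), fits the
LMM per mass, adjusts the per-iteration p values across masses by
Benjamini–Hochberg, and repeats 1000 times (desk-scale default 200). The
reported statistic is the arithmetic mean of adjusted p values over all
iterations; a mass is significant when that mean is below 0.05. Iterations
are guaranteed both groups and at least two patients by bounded resampling
(at most 100 redraws); a failed fit contributes an adjusted p of 1 — a
conservative choice that keeps the mean over exactly `n_iter` values.
Sampling follows the canonical pixel order, so results are invariant to the
row order of the matrix. The subsample is drawn per comparison (the
alternative — one global draw shared by all comparisons — would couple the
three tests without changing any single model). Log2 fold changes are
computed from pooled spectrum means per tissue (not per-patient means),
matching how mean peak heights are conventionally reported; a zero group
mean yields an undefined marker rather than an infinite fold change. The
LMM runs on raw normalized heights by default (`log2_input = TRUE` is
available), so the testing matches the scale on which fold changes are
reported.

## The synthetic generator

The generator exists so every stage can be validated against known ground
truth without patient data. For each of `n_patients × samples_per_patient`
tissue sections it:

* draws a blobby tissue map by thresholding a Gaussian-smoothed random
  field at the rank cutoffs implied by the requested class proportions
  (default NCE 0.21, stroma 0.44, cancer 0.35, mirroring the class
  imbalance of prostate MSI cohorts), inside a fixed 2-pixel matrix-only
  margin that gives matrix subtraction its source region;
* assigns each panel mass a log2 apex height
  `base + tissue_effect + patient_intercept + spatial_residual + noise`,
  rendered as Gaussian profiles with isotope satellites at
  `+k·1.00335` Da, on top of ubiquitous matrix peaks, an exponential
  baseline, additive detector noise, and a per-spectrum linear mass-scale
  error (SD 10 ppm, truncated at ±3 SD).

Defaults are 6 patients × 3 sections on 40 × 40 grids with a 30-mass panel:
eight masses carry cancer-vs-NCE effects of ±0.8 (four up, four down,
magnitudes in the range reported for citrate- and choline-like markers)
and four carry stroma effects of +0.5. Patient intercepts (SD 0.5) are
drawn per patient *and mass*: a single global per-patient factor would be
removed exactly by TIC normalization, leaving nothing for the random
effect to absorb, which real per-metabolite patient variation does not do.
Spatial residuals are Gaussian-smoothed white noise (correlation length 4
pixels), standardized to unit variance and scaled to SD 0.3; per-peak noise
has SD 0.45 on the log2 scale. The noise scales were calibrated once so
that the generator reproduces the operating regime the methods are designed
for — leave-one-patient-out OPLS-DA accuracy in the high 0.7s to low 0.9s,
planted effects flagged by the iterative LMM, VIP > 1 on effect masses —
and then frozen. Matrix-peak intensities and the baseline are set so the
chemical background dominates the TIC, as it does in real MALDI
acquisitions; this also keeps TIC normalization from distorting fold
changes (with all noise off, pipeline log2 fold changes reproduce the
planted effects to better than 0.01).

`simulate_peak_matrix()` draws extracted heights directly from the same
hierarchical model, skipping spectral rendering; it backs the Monte-Carlo
calibration studies (type-I error, VIP stability, permutation calibration)
where hundreds of replicate datasets are needed.

What the generator does **not** emulate: TOF resolution varying with m/z,
isotope fine structure, chemical-noise libraries, detector saturation, or
histology segmentation errors. Passing tests therefore demonstrate that the
statistics behave as designed under the assumed model (log-normal heights,
additive patient effects, smooth spatial residuals) — not that the pipeline
is robust to every artefact of real acquisitions.

## Numerical choices and degenerate inputs

* Apex refinement clamps the parabolic offset to half a bin; flat triplets
  fall back to the grid position.
* The REML optimizer searches `log(σu²/σe²) ∈ [−15, 10]` and compares
  against the OLS boundary, so singular fits (`σu → 0`) are valid fits.
* With one observation per patient the likelihood is flat in the variance
  split; estimates and p values then coincide with ordinary least squares,
  which the tests pin to the pooled t-test.
* Zero-variance peak columns are dropped at auto-scaling with a warning and
  excluded from VIP/fold-change joins.
* Cross-validation folds whose training set lacks a class are skipped with
  a warning rather than imputed; permutation iterations whose folds all
  degenerate count as accuracy 1 (conservative for the p value).
* All randomness flows from one root seed through named sub-streams
  (`derive_seed`), so simulation, permutation and LMM subsampling are
  independently reproducible and the pipeline is deterministic end to end.

## Problem sizes

The packaged defaults are desk-scale: `n_perm = 199` and `n_iter = 200`
(full-scale 1000/1000 are a configuration change). The validation suite
runs the complete pipeline on the default 40 × 40, 18-section scenario
(~29k spectra, ~23k annotated), and the Monte-Carlo calibrations on
24 × 24 sections via the direct peak-matrix path. These sizes were chosen
so the whole validation executes on a single CPU in minutes while leaving
the statistical contracts (±0.15 recovery, ≤0.07 type-I, ≥0.95 VIP hit
rate) testable with useful Monte-Carlo resolution.

## Known limitations

* The LMM ignores within-patient section effects; sections could be added
  as a nested random effect, but patient is the only grouping variable the
  design names.
* The permutation scheme permutes pixels, not patients; its p values are
  anti-conservative under strong spatial correlation and are reported
  alongside, not instead of, the iterative LMM.
* Identification is a static lookup (m/z → name) supplied by the user;
  no MS/MS interpretation is attempted.
* Absolute peak-selection thresholds are meaningful only on the
  base-peak-100 scale defined above; data exported on other scales need
  rescaled thresholds.
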