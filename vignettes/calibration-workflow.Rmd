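---
title: "NIRS calibration of sugarcane cell-wall traits: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIRS calibration of sugarcane cell-wall traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nirscane)
```

# The problem

Breeding energy cane for digestible biomass requires phenotyping two
cell-wall traits on thousands of samples: the cellulose crystallinity
index (CrI, %) and lignin content — acid-soluble (ASL), acid-insoluble
(AIL) and their total, expressed as % dry mass and, after dividing by
the cell-wall fraction, as % cell wall. Wet-laboratory reference assays
(X-ray diffraction, two-step acid hydrolysis) are accurate but slow;
near-infrared spectroscopy (NIRS) predicts the traits in seconds once a
multivariate calibration maps absorbance spectra, recorded as
log10(1/R) over wavenumbers, onto reference values.

`nirscane` implements that calibration workflow end to end: spectral
pretreatment, wavelength-region selection, spectral outlier screening,
partial least squares (PLS) regression with cross-validated rank
selection, internal and external validation, an exhaustive
pretreatment-by-region model search, and the statistics used to compare
two calibrations. Because no raw data accompany the study design this
package follows, every stage is exercised on synthetic data with known
latent structure, so correctness is demonstrated by parameter recovery
rather than by table matching.

# Calibration model and procedure

## Pretreatment (scatter-correction methods)

Diffuse-reflectance spectra of heterogeneous plant material carry
artifacts unrelated to composition: an additive offset, a gentle linear
baseline tilt, and a multiplicative scatter gain that scales the whole
absorbance. Ten row-wise transforms address these, named as in
commercial NIRS software:

| Method | Action |
|---|---|
| COE | subtract the row minimum (offset elimination) |
| SSL | subtract the least-squares straight line over the grid |
| SNV | center and scale each row to mean 0, sd 1 (n−1 denominator) |
| MMN | rescale each row to [0, 2] |
| MSC | regress the row on a reference spectrum, return (x − a)/b |
| FD / SED | Savitzky–Golay first/second derivative w.r.t. wavenumber |
| FD + SSL / SNV / MSC | derivative first, then the scatter correction |

Each has an exact algebraic signature, which the test suite asserts on
random spectra: SNV and MMN are invariant to positive affine maps of a
row; MSC removes exactly an (offset, gain) distortion relative to its
reference; SSL output is orthogonal to constant and linear trends; FD
annihilates constants and SED annihilates affine rows.

Numerical choices: the Savitzky–Golay filter uses window 17 and
polynomial order 2 by default (a breadth typical of commercial NIRS
smoothing; both configurable), differentiates with respect to
wavenumber so FD units are absorbance per cm⁻¹, and handles edges by
cropping half a window per side rather than polynomial extrapolation —
cropping loses 32 of 2001 points but never manufactures endpoint
values. MMN scales to [0, 2] (the vector-normalization convention of
the OPUS software family); any other range is a fixed rescaling.
The MSC reference is the mean calibration spectrum and is stored in the
fitted pretreatment spec, so validation and prediction spectra are
corrected against the calibration reference, never their own mean.

Combinations apply the derivative first, matching the "FD + X" naming.
Pretreatment operates on the full grid and the wavelength regions are
selected afterwards: selecting first would make region blocks
non-contiguous in wavenumber and poison the derivative (and give SNV/MMN
row statistics that change with the region under search).

## Region selection

The grid span is tiled into `n_intervals` contiguous equal-width blocks
(default 4) and candidate regions are unions of blocks — all 15
non-empty subsets of 4 blocks by default, mirroring the
divide-and-reassemble strategy of interval-based wavelength selection.
Intervals are closed on both ends; the table-style string format
("11,964.8 – 11,178; ...", thousands separators and either dash
tolerated, high endpoint first) round-trips through
`parse_regions()`/`format_regions()`.

## Outlier screening

Spectral outliers are flagged by the global-H statistic: a centered PCA
is fit on the pretreated, region-selected calibration spectra, the
component count is the smallest reaching 99 % cumulative explained
variance (capped at 20), and

GH_i = (1/k) Σ_j (t_ij / s_j)²,

the squared score-space Mahalanobis distance divided by the component
count; its mean over the fitting set is (n−1)/n. Samples with GH > 3
are removed once — no iterative re-elimination — and every search
candidate performs its own screening on its own pretreated matrix,
since an outlier under one pretreatment need not be one under another.
A documented alternative is a single global screening before the
search; the per-candidate form is the default because it reproduces
what an analyst does when tuning one candidate at a time.

## PLS calibration and rank selection

Single-response PLS is fit by NIPALS with deflation of X only;
components are extracted sequentially and collapsed into a coefficient
vector plus intercept, so prediction is a dot product. NIPALS models
are nested, which the cross-validation exploits: one fit at the maximal
rank yields predictions at every smaller rank. The rank (number of
latent variables, at most 25 — search default 10) is chosen to minimise
the k-fold RMSECV, ties broken toward the smaller rank. If a component's
weight norm vanishes (noiseless low-rank data), the rank is truncated
with a warning rather than dividing by numerical noise. At full column
rank PLS equals ordinary least squares, which the tests assert against
`lm()` to 1e-8.

## Validation statistics

R² = 1 − SSE/SST and RMSE = √(SSE/n) in all three roles (RMSEC on the
training fit, RMSECV on assembled out-of-fold predictions, RMSEP on an
external set whose ids must be disjoint from training). RPD is the
reference-value standard deviation of the evaluated set divided by the
corresponding RMSE, so RPD · RMSE = SD identically; RPD ≥ 2 is the
conventional screening-quality bar. The printed SD/RMSE/RPD triples in
published calibration tables are not always mutually consistent
(rounding, possibly subset-specific SDs), so this package's definition
is self-consistent rather than table-matching. R² is 1 − SSE/SST, not
the squared correlation; the two differ when predictions are biased,
and the commercial software's exact convention is unknowable.

Cross-validation uses seeded k-fold partitions (k = 10 by default; the
fold count in the original description is only "several groups").
Inside each training fold the data-dependent pretreatment parameters
(the MSC reference) are refit, so out-of-fold predictions never see
validation information; the other pretreatments are per-spectrum
transforms with nothing to fit, so pretreating once is mathematically
identical to refitting per fold and is used as a fast path. The suite
asserts the no-leakage property R²cv ≤ R² + 0.05.

## Model search and ranking

`search_models()` evaluates every pretreatment × region candidate with
its own screening and rank selection and sorts records by RMSECV
ascending, ties by higher R²cv then smaller rank — the stated selection
rule (high R², low RMSE, high RPD) needs a tie policy to be a total
order, and this one prefers accuracy, then parsimony. The winner can be
externally validated, then refit on the merged
calibration-plus-validation population (`merge_validation_and_refit()`),
reproducing the promotion of a validated equation to a global
calibration.

## Comparing two calibrations

Two calibrations (e.g. online fresh-sample vs offline dried-sample
acquisition) are compared per statistic: RMSEC/RMSECV by a two-sided
F-test, F = (max/min)² with (n−1, n−1) degrees of freedom ordered to
match; R²/R²cv through the Fisher z-transform z = atanh(√R²) with the
two-sample statistic (z₁ − z₂)/√(1/(n₁−3) + 1/(n₂−3)) referred to the
standard normal — the large-sample form of the Student comparison of
transformed correlations. Significance is starred at p < 0.05 and
p < 0.01.

# Reference assays

The Segal crystallinity index is CrI = 100 · (I₂₀₀ − I_am)/I₂₀₀, with
I₂₀₀ the maximum diffractogram intensity near 2θ = 22.5° (200
reflection, crystalline plus amorphous) and I_am the minimum between
the 200 and 110 peaks near 18.5° (amorphous only). Both extrema are
located by windowed search ([21°, 24°] and [17°, 20°], configurable)
rather than fixed-angle lookup, because real peak positions drift;
no baseline is subtracted by default (Segal's original convention),
with an optional linear-background flag. CrI is invariant to uniform
intensity scaling.

Lignin arithmetic: ASL % = 100·A₂₀₅·V·DF/(ε·l·m) with the 205 nm
absorptivity ε = 110 L g⁻¹ cm⁻¹ (the standard NREL-procedure value;
the protocol cites the procedure without printing ε);
AIL % = 100·(residue − ash)/m; the cell-wall fraction is
(dry − soluble sugar)/dry; proportions are contents divided by that
fraction, so a proportion can never fall below its content.

# What the synthetic data emulate — and what they do not

The generator defines the study conditions; its defaults are fixed
choices, not tuning knobs.

**Traits.** The four base traits (CrI, ASL, AIL, cell-wall fraction)
follow truncated normals with the published population statistics: CrI
mean 42.8, sd 3.85, range 21.6–55.6 %; ASL mean 1.73, sd 0.23, range
1.2–2.6 % DM; AIL mean 14.8, sd 2.95, range 9.2–25.3 % DM; the
cell-wall fraction (mean 0.46, sd 0.05, range 0.30–0.65) is chosen so
total lignin proportion spans its published 24.3–56.2 % CW range.
Because truncation at the published ranges would shrink the AIL sd by
about 7 %, the latent (mean, sd) of each truncated normal are solved
numerically so the *truncated* distribution reproduces the configured
moments exactly; the joint distribution is a Gaussian copula with a
modest correlation structure (ASL–AIL 0.35, lignin–cell-wall negative,
CrI largely independent) — a modeling choice, not a measured quantity.
Measurement noise (sd 1.2 CrI, 0.07 ASL, 0.9 AIL, 0.015 cell-wall
fraction) is added to produce observed values; the noiseless truth is
retained in `true_*` columns. These noise levels put the attainable
R² near var(true)/(var(true)+var(noise)) ≈ 0.91 — the generator is
documented to admit R² ≈ 0.9, consistent with high-quality published
calibrations, and leaves headroom neither for perfect recovery nor for
failure under a competent model.

**Spectra.** Absorbance of sample i at wavenumber ν is

offset_i + slope_i·(ν − ν̄) + m_i·(bg·B(ν) + Σ_t x_it·S_t(ν)) + batch shift + noise,

with Gaussian trait signature bands S_t (2–3 per trait, placed in
distinct wavelength blocks so region selection has something to find),
log-normal gain m_i = exp(N(0, 0.1)), offset sd 0.05, tilt sd 1e-5 per
cm⁻¹, six collection batches with constant-shift sd 0.02, and
heteroscedastic channel noise sd 0.002·(1 + 0.5·|clean|). B(ν) is a
fixed broad matrix background of magnitude ≈ 0.5 inside the gain: real
spectra are dominated by a common matrix absorbance, and it is this
component that lets SNV/MSC estimate the per-sample gain — without it a
10 % gain error on a trait whose mean is ten times its sd destroys
absolute quantification no matter the model, and scatter corrections
cancel the very signal they should rescue. Setting
`background_amplitude = 0` recovers the bare band-only model, which the
proportionality tests use. The default grid is 4000–12,000 cm⁻¹ at
4 cm⁻¹ (2001 points), covering both the stated scanning band and the
wavelength ranges printed in published calibration tables, which extend
to ~11,972 cm⁻¹ — the package supports any grid and does not resolve
that discrepancy.

Not emulated: physically meaningful band assignments for
lignin/cellulose chemistry, instrument line shapes, wavelength-dependent
scatter (the gain is flat), drift within a batch, or nonlinear
detector response. Passing recovery tests therefore shows the pipeline
is correct and self-consistent under a realistic artifact family — not
that it would achieve the same statistics on real bagasse.

**Diffractograms.** A constant background plus two crystalline
Gaussian peaks (200 at 22.5°, 110 at 15.5°, amplitude ratio 0.55) and a
broad amorphous component (center 21°, width 8°): the curve's maximum
falls on the 200 peak and its minimum lands between the 110 and 200
peaks near 18.5°, as the Segal convention requires. The amorphous
amplitude is solved by root finding so the noiseless curve returns the
target CrI within 0.1 — closure by construction, verified for CrI 25,
42.8 and 55. At very low CrI the located minimum drifts toward the
lower window edge; within the population range (21.6–55.6 %) it stays
near 18.5°.

**Wet chemistry.** Records (A₂₀₅, volumes, masses) are built by
inverting the assay arithmetic, so zero-noise recovery is exact to
1e-10; defaults add 1 % relative noise on A₂₀₅ and 0.2 mg on weighed
masses, mean-zero, so recovery is unbiased.

All generators are bit-deterministic given (config, seed); the pipeline
derives per-stage substreams from one master seed so modules are
independently reproducible.

# Problem sizes and runtime posture

The packaged study runs 300 samples × 2001 wavelengths, a 240/60
calibration/validation split (one-fifth held out, the same proportion
as 120 of 838), 10 pretreatments × 15 region subsets per trait, 10-fold
CV, ranks up to 10, GH threshold 3. These sizes make the full search
(300 candidates across two traits) a few minutes of computation while
keeping every statistic stable; they are deliberate analysis choices,
stated here so the reported numbers are interpretable. The original
population scale (838 samples) appears in the sample bookkeeping
functions, not in the simulations.

# Known limitations

* Single-response PLS only (no PLS2), no robust PCA, no
  bias/SEP-decomposed validation statistics or RER/RPIQ metrics.
* The Fisher-z comparison treats the two calibrations as independent
  samples; comparing two models fit on the *same* samples violates that
  assumption and the test is then conservative at best.
* The region-subset policy enumerates unions of equal-width blocks; it
  does not search arbitrary interval endpoints, so published
  free-endpoint regions can only be approximated by blocks.
* JCAMP-DX support covers the plain two-column AFFN payload with `##`
  headers, not compressed dialects or vendor binary formats.
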