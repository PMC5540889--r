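---
title: "Methods: from hyperspectral cubes to leaf chemistry models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from hyperspectral cubes to leaf chemistry models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperleaf)
```

## The measurement problem

A push-broom imaging spectrometer in a greenhouse phenotyping chamber
records, for each potted plant, a cube of raw 16-bit digital numbers (DN):
scan lines × detector pixels × spectral bands. The instrument modeled here
spans 550–1700 nm in 243 bands and images a 2500 mm × 1600 mm chamber at
5 mm square pixels (500 × 320). Immediately after each plant, the empty
carrier is imaged under the same lamps as a *reference scan*. The goal is a
per-plant estimate of leaf water content and of 12 nutrient concentrations,
calibrated against destructive laboratory chemistry on a subset of plants.

The chain is: normalize → segment → average → regress. Each stage is a
small, separately testable operation.

## Spectral axis

The wavelength grid is defined by its band count (243) and its two
endpoints (550 and 1700 nm), both taken as exact; the spacing follows as
1150/242 ≈ 4.752 nm. An instrument's nominal band interval (≈ 4.77 nm for
this class of spectrometer) is deliberately *not* used to generate the
axis: 243 bands at 4.77 nm starting at 550 nm would overshoot 1700 nm, so
count and endpoints are treated as the hard constraints and the interval as
descriptive. Band lookup (`nearest_band`) takes the center closest to a
target wavelength, breaking exact ties toward the lower index; this matters
because 705 and 750 nm — the NDVI bands — do not fall exactly on the grid
(the nearest centers are ≈ 706.8 and ≈ 749.6 nm).

## Normalization and its assumptions

Apparent reflectance is the per-voxel ratio of plant DN to reference DN.
Because both scans share the lamp spectrum and the spatial illumination
field, the ratio cancels them exactly — a property the simulator makes
testable (rendering the same plant under a flat field and under a field
varying twofold across the chamber yields the same extracted spectrum up to
DN rounding). Two numerical choices:

- Ratios are clipped to [0, 1] after division. Specular highlights can push
  the raw ratio above 1; the pre-clip values are not retained. This is a
  package choice: the workflow treats reflectance as fractional by
  contract.
- Voxels with a zero reference DN carry no information and are flagged
  invalid rather than clipped or set to infinity. Invalid voxels are
  excluded from NDVI eligibility and from every downstream average; a band
  with no valid masked pixel is reported as `NA` and dropped from modeling
  rather than imputed.

## Segmentation

The NDVI image `(I750 − I705)/(I750 + I705)` separates vegetation (strongly
positive across the red edge) from pot, carrier and belt (near zero). A
single universal threshold of 0.20 is applied with a *strict* inequality;
pixels exactly at the threshold are background. No morphological cleanup
(erosion, hole filling) is applied — segmentation is thresholding only, so
the mask is exactly reproducible from the NDVI image. An empty mask is a
legal segmentation result but an error at spectrum extraction, reported
with the plant identifier so a failed plant is traceable in batch runs.

## PLS1 calibration

One model per trait (traits have different information content and earn
different model sizes), fit by NIPALS PLS1 on mean-centered, unscaled
spectra. Centering-only is the standard treatment when all predictors share
one unit (reflectance); autoscaling would inflate noise-only bands. For a
univariate response the NIPALS iteration is closed-form per factor:

- weight `w_a ∝ X'y` (the covariance direction),
- score `t_a = X w_a`, loading `p_a = X't_a / t_a't_a`,
- response loading `q_a = y't_a / t_a't_a`, then deflation of `X` and `y`.

Regression coefficients for any truncation `a` are accumulated through the
basis `r_a = w_a − Σ_j (p_j'w_a) r_j`, giving the whole coefficient path
from one fit. The implementation is deterministic (no random
initialization) and truncates with a warning when the deflated spectra run
out of usable rank. At full rank the predictions provably coincide with
ordinary least squares, which the test suite checks against `lm.fit` on
random instances; an independent PLS implementation (mixOmics) is used as a
cross-check oracle in one test and nowhere else.

### Factor selection

The factor count is selected by leave-one-out cross-validation on the
calibration half: for `a = 1..A` each plant is held out, the model refit,
and the plant predicted; `RMSE_CV(a)` is the root mean squared error of the
held-out predictions and the selected size is the smallest `a` attaining
the minimum (parsimony on ties — relevant because rank-deficient curves go
exactly flat past the true rank). `A` is capped at 12 — latent dimensions
beyond that are noise-chasing for spectra of this kind — and additionally
at `n − 2` so every fold remains fittable, and at the band count.

### Split and screening

The calibration/validation split is stratified over species × experiment ×
treatment so every cell is represented as evenly as parity allows; the
per-stratum rounding remainder is carried across strata, so the overall
split hits the requested fraction (60/60 for the default design) even
though 15-member cells individually split 7/8. The split is a deterministic
function of its seed. A per-trait Welch two-sample test then compares
calibration and validation means — advisory only, no multiplicity
correction, α = 0.05 — mirroring the balance table a study of this design
would report. PCA screening (mean-centered, first three components, 3 SD
score limit) flags suspicious spectra but retains them by default; the
`drop` policy is a config switch. Flag-and-retain is the right default
because a spectral outlier with ordinary chemistry is usually a real plant,
not an artifact.

## Evaluation statistics

For each trait and phase (LOOCV held-out predictions; untouched validation
half):

- `RMSE` uses divisor N. `RPD = SD/RMSE` uses the *sample* SD (divisor
  N−1), the chemometrics convention; mixing the two conventions shifts RPD
  in the second decimal at N = 60, so the package fixes them explicitly and
  tests the exact identity `RPD × RMSE = SD(y)`.
- `MAPE` divides the mean absolute error by the *mean of the evaluated
  set's measured values* — not the classic per-observation percentage.
  This keeps the statistic finite for traits with near-zero individual
  values (sodium) and is the definition used in this workflow's field.
- `R²` defaults to the squared Pearson correlation between measured and
  predicted; `1 − SSres/SStot`, which additionally penalizes bias, is
  exposed as `r2_mode = "one-minus-ssr"`. Which of the two a given report
  means is often ambiguous in the literature; both are provided and the
  default documented.
- RPD bands: < 1.5 poor; 1.5–2.0 fair/screening; 2.0–3.0 good; > 3.0
  quantitative. Band edges belong to the lower band (2.0 is
  "fair/screening").

A perfect model (RMSE = 0) has no finite RPD and is signalled as an error
rather than returned as `Inf`, so report code cannot silently propagate it.

## The simulator: what it emulates, and what it does not

The simulator exists so every stage — including the full
cubes-to-report chain — is testable without instrument data. Its defaults
are the study conditions, not tuning knobs:

- **Design**: 120 plants; per species (maize, soybean), a water experiment
  (15 control / 15 water-limited) and a nutrient experiment (10 each of
  low/medium/high fertilizer).
- **Chemistry**: treatment-shifted Gaussians truncated at frozen pooled
  ranges — maize water content within 79.6–91.0%, soybean within
  68.2–81.9%, nitrogen within 0.96–5.68% — with low < medium < high means
  for nutrient-responsive traits. Sodium and boron get no treatment effect.
  Dry weight is derived from fresh weight and the target water content, so
  `WC = (W_fresh − W_dry)/W_fresh × 100` holds exactly by construction.
- **Spectra**: a smooth species baseline (low VIS, red edge near
  700–750 nm, NIR plateau, water troughs at 970/1240/1450 nm with 1450 the
  deepest) plus a *linear* trait term: `baseline + L (x − x_ref) + noise`,
  clipped to [0.01, 0.99]. Water content deepens the water troughs;
  nitrogen deepens visible chlorophyll absorption; each remaining loaded
  trait has its own band signature; sodium and boron have zero loading.
  The loading calibration is frozen in a versioned file
  (`inst/extdata/spectral_loadings_v1.json`) so simulated studies are
  comparable across seeds; per-band spectral noise defaults to 0.002
  reflectance units.
- **Scene**: plant silhouette over a flat background reflector at 0.05
  (low NDVI, so segmentation is exercised nontrivially but never captures
  background); a strictly positive illumination field (broad hot spot,
  default ±30% over base) shared by plant and reference scan; a 2600 K
  Planck lamp spectrum; detector noise (default SD 30 DN on a 40000 DN
  full scale); rounding to 16-bit DN.

Deliberate simplifications, and what they imply for test evidence:

- The chemistry→spectrum map is linear, so PLS recovery is achievable by
  construction. Passing the end-to-end recovery tests shows the pipeline is
  correct and unbiased, *not* that real leaf tissue — with nonlinear
  radiative transfer, canopy geometry, and specular effects — would be
  predicted at the same accuracy. Simulated validation accuracies are an
  upper bound; the meaningful structural result is the contrast between
  spectrally loaded traits (recovered, R² > 0.9) and silent ones (honestly
  failed, R² < 0.1, RPD ≈ 1).
- Chemistry is whole-plant constant per pixel (the workflow predicts one
  value per plant); within-plant gradients and per-pixel prediction are out
  of scope.
- The background spectrum is an invention (flat 0.05); real pot/belt
  spectra are not characterized. The manifest labels it synthetic.
- No radiative-transfer leaf model (PROSPECT-style), no 3-D canopy, no
  temporal growth.

## Problem sizes and determinism

Default simulated cubes are 48 × 32 × 243 — the full spectral axis at
desk-scale spatial extent; the test suite uses 12–24 line scenes and the
acceptance script the 48 × 32 default, sizes chosen so a complete
simulate–process–fit–evaluate cycle runs in well under a minute on one
core while still exercising every code path at the instrument's band
count. All randomness (chemistry, spectral noise, detector noise, split)
descends from a single integer seed; per-plant seeds are drawn once from
the master seed, and rendering, processing and modeling are deterministic
given them, so bundles are byte-reproducible. Functions that consume
randomness restore the caller's RNG state.

## Known limitations

- BIL is the only supported interleave (BIP/BSQ cubes must be converted
  upstream); headers are a minimal ENVI dialect with unknown keys preserved
  verbatim.
- Reflectance clipping at 1 discards specular-highlight information rather
  than modeling it.
- The Welch balance check and the PCA outlier flags are advisory; nothing
  re-splits or re-fits automatically.
- Within-species submodels reuse the global split restricted to one
  species; for very small per-species designs the halves can be slightly
  uneven.
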