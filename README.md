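# hyperleaf

In vivo estimation of leaf chemical traits — water content and 12
macro-/micronutrient concentrations — from greenhouse hyperspectral images
of single plants. The package is aimed at high-throughput phenotyping
groups who image potted plants on a conveyor with a push-broom VNIR/SWIR
spectrometer (550–1700 nm, 243 bands) and want calibrated, validated
per-trait prediction models rather than raw vegetation indices.

## What it does

1. **Cube I/O** — reads and writes 16-bit ENVI-style BIL image cubes with
   their text headers, bit-exactly.
2. **Image pipeline** — converts a plant scan plus its paired blank-chamber
   reference scan into one apparent-reflectance spectrum per plant:

   - band-by-band normalization `R = DN_plant / DN_reference`, clipped to
     [0, 1] (the shared reference cancels the lamp spectrum and the
     non-uniform illumination field);
   - red-edge NDVI image `(I750 − I705) / (I750 + I705)` from the grid
     bands nearest 705 and 750 nm;
   - vegetation segmentation at the universal threshold NDVI > 0.20;
   - masked per-band averaging into a 243-point mean spectrum.

3. **Chemometrics** — PCA outlier screening (flag-and-retain), a stratified
   50/50 calibration/validation split balanced over species × treatment
   (with a Welch-test balance report), and per-trait PLS1 regression
   (NIPALS, mean-centered, unscaled) with the factor count `a ≤ 12` chosen
   by leave-one-out cross-validation:

   `a* = argmin_a RMSE_CV(a)`, smallest `a` on ties.

4. **Evaluation** — the standard chemometric statistics per trait and
   phase (cross-validation and independent validation):

   - `RMSE = sqrt(mean((y − ŷ)²))` (divisor N),
   - `RPD = SD(y) / RMSE` (sample SD, divisor N−1),
   - `MAPE = mean(|y − ŷ|) / mean(y) × 100` (set-mean normalized),
   - `R²` as squared Pearson correlation (with `1 − SSres/SStot` as an
     option),

   plus the usual RPD quality bands: < 1.5 poor, 1.5–2.0 fair/screening,
   2.0–3.0 good, > 3.0 quantitative.

5. **Simulator** — a synthetic greenhouse imaging study: a 120-plant
   two-species design (water-limitation and nutrient-level experiments),
   chemistry-driven spectra (water content deepens the 970/1240/1450 nm
   water absorption troughs, nitrogen the visible chlorophyll absorption;
   sodium and boron are spectrally silent by construction), halogen-lamp
   illumination with a non-uniform gain field, detector noise, and full
   BIL rendering — so the entire pipeline is testable end to end without
   any instrument data.

## Worked example

Simulate a small study (44 plants, desk-scale cubes), process it, and fit
models for water content, nitrogen, and the spectrally silent sodium:

```r
library(hyperleaf)

cfg <- run_config("readme_demo", seed = 11,
                  sim = list(n_water = 5L, n_nutrient = 4L,
                             n_lines = 24L, n_samples = 20L))
cmd_simulate(cfg)     # writes 44 plant + 44 reference BIL cubes
cmd_process(cfg)      # 44 rows x 243-band spectra.csv
fit <- cmd_fit_evaluate(cfg)

subset(fit$report, phase == "validation" & trait %in% c("wc", "n", "na"))
```

```
 trait  n      r2    rmse    rpd   mape model_size
    wc 22 0.99805 0.24050 23.112  0.237         11
     n 22 0.97566 0.17674  5.997  4.006         10
    na 22 0.00571 0.00337  0.915 34.095          7
```

Reading the rows: on the 22 held-out validation plants, water content (in %
of fresh weight) is recovered almost perfectly — R² = 0.998 with an RMSE of
0.24 percentage points, an RPD of 23 (`classify_rpd` → "quantitative"), and
a mean absolute error of 0.24% of the set mean. Nitrogen (% of dry mass)
is also quantitative. Sodium carries no spectral signature in the
simulator, and the model honestly fails on it: R² ≈ 0.006 and RPD ≈ 0.9
("poor"), i.e. no better than predicting the mean. The `model_size` column
is the LOOCV-selected latent factor count. The simulator's linear
chemistry-to-spectrum map and whole-plant-constant chemistry make these
accuracies an upper bound on what real leaf tissue would give; the
contrast between loaded and silent traits is the structurally meaningful
result.

`fit$report` also contains the cross-validation rows, `fit$balance` the
per-trait Welch balance check of the split, and `fit$scatter` the
measured-vs-predicted pairs for scatterplots.

A thin command-line wrapper is included at `inst/cli/hyperleaf.R`
(`simulate` / `process` / `fit-evaluate` subcommands driven by a JSON
config).

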