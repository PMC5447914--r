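---
title: "Calibrating NIR moisture prediction for intact green coffee beans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating NIR moisture prediction for intact green coffee beans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the methods implemented in `nirmc`: what each stage
of the workflow computes, which parameters control it (with units and
defaults), and where the numerical choices come from. The worked example in
the README shows the same pipeline end to end; here the focus is on the
methods themselves.

```{r setup}
library(nirmc)
```

## The measurement problem

Moisture content (MC) of green coffee determines storability and tradability:
the commercial safety range is 8.0–12.5 % wet basis (`classify_safety()`
treats both boundaries as in range). The reference method is gravimetric
oven drying: a sample is weighed wet (`ww`, g) and after drying (`wd`, g),
and `mc_wet_basis()` computes `(ww - wd) / ww`, the mass fraction lost,
reported here in percent of fresh mass. Each sample is dried in duplicate;
`summarize_duplicates()` averages the two determinations into the reference
value and records the per-sample SD, whose average (about 0.21 % MC under the
defaults) measures the precision floor of the reference method. No
calibration can be validated below that floor.

The spectral measurement is near-infrared diffuse reflectance of intact
beans, expressed as apparent absorbance log(1/R) on a grid of 1557 points
spanning 1000–2500 nm. The grid is uniform in *wavenumber* (10000 to
4000 cm⁻¹), which is why its spacing in nm grows from about 1 nm at the short
end to about 2.4 nm at the long end; `default_grid()` constructs it and every
spectra tibble carries it in its column names.

## Data model

A spectra tibble has six metadata columns (`sample_id`, `species`, `origin`,
`replicate`, `role`, `mc`) followed by one numeric column per wavelength.
Everything downstream — preprocessing, models, plots — operates on this one
shape, and `read_spectra()` / `write_spectra()` round-trip it through wide
CSV exactly. A minimal JCAMP-DX reader (`dialect = "jcampdx"`) covers
single-spectrum instrument exports.

Three replicate spectra are recorded per sample and averaged
(`average_replicates()`) before modelling; averaging attenuates the
per-replicate scatter and noise by about √3. The calibration/validation
split is by *origin* (`split_by_origin()`): validation origins are entirely
unseen during calibration, which is a stricter and more honest test than a
random sample split, because it requires the model to transfer across
growing regions.

## Preprocessing

All stateless treatments (`smooth_spectra()`, `sg_derivative()`,
`normalize_spectra()`, `baseline_correct()`, `snv()`) operate row-wise and
preserve the grid. Windowed filters use reflection padding so the output
length equals the input length. Savitzky–Golay derivatives
(`signal::sgolay`) are taken with respect to grid index, not nm, because the
grid is non-uniform in nm; for peak-shape purposes this only rescales the
derivative smoothly.

Two treatments are *fitted*, not stateless:

* **MSC/EMSC** (`fit_scatter()`): each spectrum `x` is regressed on
  `a + b·ref + c₁λ̃ + c₂λ̃²` (λ̃ is wavelength mapped affinely to [−1, 1]; MSC
  uses only `a + b·ref`) and corrected as `(x − a − Σcᵢλ̃ⁱ)/b`. The reference
  `ref` defaults to the calibration mean spectrum. EMSC inverts its
  distortion model *exactly* when the spectrum truly is an offset/multiple
  of the reference plus a polynomial — the acceptance suite verifies this at
  machine precision on a noise-free constant-chemistry dataset. On real
  heterogeneous data the chemistry differs from the reference, so the
  correction is only approximate and the multiplicative coefficient `b̂` can
  absorb genuine signal; this is why raw-spectrum PLSR is always kept as the
  baseline for comparison.
* **OSC** (`fit_osc()`): removes the dominant spectral variation orthogonal
  to the response before calibration. The stored weights reproduce the
  deflation on new data. With more wavelengths than samples the removed
  score is exactly orthogonal to `y`.

Fitted state always comes from calibration data only and is reused unchanged
on validation data (`fit_preprocessor()` / `predict()`), which makes
train/validation leakage structurally impossible.
`compare_preprocessing()` screens the full catalogue
(`default_preprocessing_grid()`: 3 smoothers × 5 windows, 3 derivative
configurations × windows, normalisations, baselines, SNV, MSC, EMSC,
OSC) by leave-one-out RMSECV — reproducing the common finding that raw
spectra calibrate as well as pre-treated ones when scatter is mild.

## Outlier screening

`fit_pca()` computes mean-centred PCA by NIPALS — components extracted one
at a time with deflation, so only the two components needed for screening
are computed. Each sample's Hotelling T² is its squared score distance
scaled by component variances, and the control limit
(`hotelling_limit(n, p, alpha)`) is `p(n−1)/(n−p)·F₁₋α(p, n−p)` — the "5 %
ellipse" on score plots at the default `alpha = 0.05`. Crucially, flagged
samples are not dropped automatically: `keep_or_drop()` refits the
calibration with and without them and recommends dropping only when RMSECV
improves by more than 10 % (relative), mirroring the conservative practice
of keeping unusual but valid samples.

## Calibration models

* **PLSR** (`fit_plsr()`): univariate NIPALS partial least squares on
  mean-centred spectra, no variable scaling. With one response the weight
  step is closed form, so no inner iteration is needed. The coefficient
  vector is `b = W(PᵀW)⁻¹q`.
* **Full cross validation** (`full_cross_validation()`): leave-one-out, with
  the model *refitted from scratch* (including re-centring) for every
  held-out sample; predictions at every latent-variable count come from one
  `max_lv` fit per fold. `choose_n_lv()` applies a parsimony rule: the
  smallest count whose RMSECV is within 5 % (relative) of the curve minimum.
* **MLR** (`fit_mlr()`): ordinary least squares with intercept on a small
  set of selected wavelengths, via QR; rank deficiency is an error that
  names the aliased columns. `leverage_corrected_rmse()` computes
  `sqrt(mean((e/(1−h))²))`, which by the PRESS identity *equals* exact
  leave-one-out for OLS — the acceptance suite checks this against a
  brute-force refit loop at 1e−8.

## Wavelength selection and the published model

`select_wavelengths()` operationalises coefficient-trace peak picking: local
maxima of |b|, greedily keeping the `k = 7` largest subject to a minimum
pairwise separation (default 20 nm), ties broken toward the lower
wavelength. The selected columns feed `refit_subset()` (MLR or 3-LV PLS).

`published_moisture_model()` carries the reported seven-wavelength model
(1155, 1212, 1340, 1409, 1724, 1908, 2249 nm) with its printed intercept
(−4.20 % MC) and coefficients, frozen exactly; `published_predict()`
evaluates it. These constants are the package's only tie to the original
study's unreleased data.

## Validation statistics

`evaluate_predictions()` computes, with residuals `e = ŷ − y`:
bias = mean(e); RMSEP = √mean(e²); SEP = SD(e) with n−1 denominator;
R² = 1 − SSE/SST; RPD = SD(y_ref)/SEP. These satisfy
`RMSEP² = bias² + SEP²·(n−1)/n` identically. A perfect prediction yields the
sentinel `RPD = Inf`, which `report_table()` prints as `"Inf"` rather than
dropping. `compare_prediction_errors()` tests whether two models differ: a
paired t-test on per-sample squared residuals, or a sign-flip randomization
alternative that avoids the normality assumption.

## The synthetic data generator

The original spectra are not released, so `simulate_dataset()` provides a
study-structured stand-in used by the tests and the acceptance targets. What
it emulates:

* the sampling design — 108 samples (64 calibration / 44 validation) from 12
  origins of two species, 3 replicate spectra each, duplicate gravimetric
  weighings around 10 g;
* chemistry as Gaussian absorption bands on a smooth background: two water
  bands (1450, 1940 nm) carrying most of the moisture signal, plus
  constituent bands near the published wavelengths carrying weaker indirect
  moisture information and the Arabica/Robusta contrast; a broad
  species-level difference makes species the dominant direction of spectral
  variance (PC1+PC2 ≈ 99 %), as observed for commercial coffee;
* measurement physics as per-replicate EMSC-form scatter (offset
  a ~ N(0, 0.02), multiplier b ~ N(1, 0.05), order-2 polynomial baseline)
  plus additive noise (SD 0.002 absorbance);
* reference-method precision: duplicate MC noise is drawn with
  SD = 0.21/c₄(2), where c₄(n) is the normal-SD bias constant
  (`c4_const()`), so the *expected sample SD* equals the 0.21 % MC target —
  drawing at 0.21 directly would undershoot by the factor
  c₄(2) = √(2/π) ≈ 0.80.

What it does not emulate: instrument drift, temperature effects, bean-size
and packing-density variation, water-activity hysteresis, or any
non-Gaussian band shapes. Its error magnitudes are therefore optimistic
relative to the published ones, and the acceptance criteria treat the
published RMSEPs as *upper bounds* for the simulation analogue, not as
values to match.

Reproducibility: a single integer seed drives four fixed per-stage RNG
streams (`seed*8 + stage` for true MC, duplicates, scatter, noise), so
identical `(config, seed)` is bit-identical, and changing one stage's
parameters leaves the other stages' draws untouched.

## The orchestrated pipeline

`run_workflow(workflow_config(...))` runs the whole study deterministically:
simulate or load data, recompute reference MC from weighing records, average
replicates, screen outliers (PCA + T² + keep-or-drop), optionally screen
pre-treatments, fit the four model configurations (raw 3-LV PLSR, EMSC 4-LV
PLSR, 7-wavelength MLR, 7-wavelength 3-LV PLS), validate on the held-out
origins, and emit the side-by-side report table, pairwise error tests, and a
run log — written as CSVs when `outdir` is set. This function is the
package's command-line entry point: an `Rscript` one-liner around
`run_workflow()` replaces any bespoke shell interface, and
`scripts/acceptance.R` is exactly such a wrapper for the acceptance targets.

## Numerical choices and test scale

* NIPALS (PLS, PCA) is used instead of one-shot SVD because it is the
  standard chemometric algorithm, extracts only the components requested,
  and makes deflation explicit; agreement with `eigen`/`lm` at 1e−6–1e−8 is
  enforced by oracle tests.
* OSC weights use an SVD pseudoinverse (minimum-norm solution), which is
  well-defined for wide matrices where `qr.solve` is not.
* The EMSC polynomial basis uses λ̃ ∈ [−1, 1] for conditioning.
* Unit tests run on a reduced 160-point grid with the full 108-sample
  design, so every pipeline path is exercised in seconds; the acceptance
  tests and `scripts/acceptance.R` use the full 1557-point grid, 10 seeds
  for model-performance medians and 20 for the duplicate-SD check.

## Limitations

The generator's band library is a deliberately simple surrogate: its
constituent-band moisture sensitivities are small and its noise well
behaved, so simulated RMSEPs (≈ 0.3 % MC) are lower than the published ones
(0.4–0.8 % MC). The package's claims are therefore structural — the methods
are implemented exactly and verified against oracles and printed constants —
not a reproduction of the original error magnitudes, which would require the
unreleased spectra.
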