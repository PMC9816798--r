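---
title: "Methods: grid-scale winter wheat yield estimation from reflectance time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-scale winter wheat yield estimation from reflectance time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Winter wheat yield varies strongly within a single field. With gridded harvest
measurements (here a 5 m grid, yields between 1.39 and 6.75 t/ha) as labels
and satellite reflectance as predictors, yield estimation becomes a supervised
regression problem on two kinds of inputs:

* **multispectral time series** — eight broad bands (blue, green, red, three
  red-edge bands, wide NIR, SWIR) observed repeatedly over the
  October–June growing season, summarized as four vegetation indices per
  month;
* **single-date hyperspectral spectra** — 163 narrow bands spanning
  396–2501 nm, from which two-band indices are screened exhaustively for
  yield correlation.

`wheatyield` implements the full analysis as a tested pipeline: synthetic
scene generation, feature construction, model fitting (an LSTM sequence
regressor plus random forest, gradient boosting and support vector
baselines), metric evaluation, permutation feature importance,
management-factor summaries and gridded map export.

## The synthetic scene generator

The original field campaign's raw data are not deposited, so every stage here
runs on synthetic scenes whose statistical structure matches what the
analysis assumes. The generator is a first-class, tested module, not a
fixture; all of its defaults *are* the study conditions.

**Yield grid.** A radial dome (centre-high, edge-low — the pattern managed
plots show from edge effects) plus spatially correlated Gaussian noise
(white noise smoothed with a 5-cell moving average), linearly rescaled into
the configured `[yield_min, yield_max]` = [1.39, 6.75] t/ha. A flat,
noiseless configuration degenerates to the range midpoint. The default grid
is 25 × 40 = 1,000 cells so the test suite stays fast; the campaign scale
(~15,700 cells) is one config away.

**Multispectral series.** The paper-analogue inputs are generated through a
latent-trait model: two canopy latents, *greenness* and *water status*,
follow fixed seasonal phenology shapes (dormant winter, spring green-up,
heading peak, senescence) scaled by an affine function of each cell's yield.
Band reflectances are affine maps of the latents with signs chosen so the
downstream indices behave like their field counterparts: SR and EVI rise
with greenness, NDWI rises with water, and the red-edge position shifts with
greenness (the first red-edge band's position between red and NIR is itself
greenness-dependent — without that nonlinearity REP would be constant by
construction). Gaussian reflectance noise (default sd 0.01, a typical
surface-reflectance error magnitude) is added per scene and values are
clamped to [0, 1]. Because the band-to-index maps are monotone but not
linear in yield, the noiseless SR–yield link is rank-perfect (Spearman 1)
rather than Pearson-perfect; tests assert exactly that.

**Cloud cover.** Each month carries several acquisitions; every scene draws
cloud cover from a two-component mixture (70% clear: U(0, 25)%; 30% cloudy:
U(35, 90)%), so the 30% filter always has both kept and discarded scenes to
work on.

**Hyperspectral spectra.** A smooth vegetation baseline (visible trough with
green bump, red-edge rise, NIR plateau, SWIR decline with the 1450/1940 nm
water absorptions) is shared by all samples; band noise is added; then each
*planted pair* `(i, j, sign)` receives a yield-linked perturbation `±amp ×
(y_norm − 0.5)` added to band `i` and subtracted from band `j`. All three
two-band families (difference, ratio, normalized difference) of a planted
pair then correlate with yield with the requested sign, and no other band
carries signal. The defaults plant one visible/NIR pair (516/765 nm,
negative) and one SWIR pair (1375/1896 nm, positive), mirroring the sign
structure reported for winter wheat canopies. The band grid is 76 VNIR
bands (396–1040 nm) plus 90 SWIR bands (1006–2501 nm) minus the 3
overlapping SWIR bands = 163 effective bands.

**Management table.** Yields are drawn from an additive effects model:
seeding rate follows an inverted U peaking at 225 kg/ha; irrigation raises
yield monotonically to +0.5 t/ha at 60 mm; rotational tillage (+0.35 t/ha)
and variable-rate fertilization (+0.30 t/ha) carry the categorical effects;
residual noise sd 0.25 t/ha. Zeroing the effects gives a null experiment.

**What the generator does not emulate.** No radiative-transfer physics, no
per-pixel cloud masks, no sensor point-spread or co-registration error, no
spatial autocorrelation between a cell's reflectance and its neighbours'
beyond the yield field itself. Passing tests therefore demonstrate that the
*pipeline* recovers structure it is designed to detect — not that the models
would reach any particular accuracy on real imagery.

## Vegetation indices and compositing

The four indices are the canonical published forms:

* EVI = 2.5 (B8 − B4) / (B8 + 6 B4 − 7.5 B2 + 1)
* SR = B8 / B4
* NDWI = (B8 − B11) / (B8 + B11)
* REP = 705 + 35 · (0.5 (B4 + B7) − B5) / (B6 − B5) (nm)

Each guards its denominator: values within 1e−9 of zero flag the result as
missing rather than erroring, so a bad scene degrades gracefully. When the
REP interpolation term vanishes (0.5 (B4+B7) = B5) the index sits exactly at
705 nm, the anchor wavelength of the linear-interpolation construction.

Compositing computes each index **per scene first**, then averages retained
scenes within a month (not bands first): scenes with cloud cover *strictly
greater* than 30% are discarded — a scene at exactly 30.0% is retained, the
documented boundary convention. A month with no retained scene is filled by
linear interpolation between neighbouring months, with constant
extrapolation at the season edges; this choice (the source analysis is
silent) keeps the LSTM input dense. A season with no usable scene at all is
a hard error.

Flattening for the non-sequence baselines is **index-major**: all months of
EVI, then SR, NDWI, REP — 4 × 9 → 36, and 3 × 4 → 12 for the hyperspectral
variant. The order is fixed and invertible (`unflatten_vi_matrix()`) so
baseline experiments are reproducible.

## Two-band index screening

For spectra R and any band pair (i, j): SSI = Ri − Rj, RSI = Ri / Rj,
NDSI = (Ri − Rj)/(Ri + Rj). The screening correlates each pair's index with
yield across samples (Pearson, the form in which signed correlation
coefficients are reported in this literature) and attaches two-sided
p-values from the t distribution with n − 2 degrees of freedom. SSI and
NDSI are antisymmetric under band exchange — r(i, j) = −r(j, i) — so their
searches run over the 163·162/2 = 13,203 unordered pairs; RSI is not
symmetric and is searched over ordered pairs. Selection takes the most
positive and most negative correlations among pairs with p < 0.001, ties
broken toward the smaller band indices; an empty sign slot warns rather
than fails. The pair with the largest |r| per family defines that family's
custom feature, evaluated on each acquisition date to give the 3 × 4
hyperspectral model input.

## Models

**LSTM.** Input sequences are time-major (`samples × months × indices`).
Two stacked LSTM layers of 100 units feed the final hidden state through a
ReLU and a dense head to one yield value. The cell follows the standard
gate equations (`lstm_cell_step()` exposes them literally and the vectorized
trainer is tested against it, and against finite-difference gradients).
Training: MSE loss, L2 penalty on all weight matrices (default 1e−4 — the
coefficient is not specified in the source analysis and is configurable),
inverted dropout 0.3 on each layer's outputs (fresh masks per timestep),
Adam (the conventional choice; the optimizer is otherwise unspecified) at
learning rate 0.001, batch size 64, a fixed 700 epochs with no early
stopping. Features and target are z-scored on the training split and the
transform inverted at prediction. Initialization is uniform ±1/√H, fully
seed-controlled; training is bit-reproducible. A non-finite loss aborts
with a diagnostic rather than returning a broken model.

**Baselines.** The flattened 36-vector (or 12 for the hyperspectral
variant) feeds: random forest (150 trees, fit seed 200, out-of-bag MSE and
R² recorded), gradient-boosted trees (1250 rounds, subsample 0.6, learning
rate 0.1, depth-3 trees, single-threaded for determinism) and RBF support
vector regression (C = 1e5, gamma = 0.5) on z-scored features — at that
gamma the kernel is sharply local, so standardization is load-bearing. If
every target lies inside the ε-tube the SVR backend has no support vectors
and cannot predict; the wrapper then falls back to the mean target, which
is what the ε-insensitive loss implies.

**Split and metrics.** A seeded random 9:1 partition (disjoint, exhaustive);
evaluation reports MAE, RMSE and R² = 1 − SSres/SStot on the held-out 10%.
RMSE ≥ MAE always (power-mean inequality, asserted property-based); a
zero-variance truth flags R² as undefined instead of dividing by zero.

## Permutation feature importance

After training once, each feature's **whole trajectory** is permuted across
samples (within-sample temporal structure preserved — "one vegetation index
feature at a time"), predictions are recomputed without retraining, and the
increase in loss (MSE by default; configurable) measures importance. For
flattened inputs all columns of a feature are permuted jointly with one
permutation. The shuffle is repeated (default 10; a single seeded shuffle
via `n_repeats = 1`) and the mean reported; features are ranked by
descending loss. On generator data with one dominant index, that index
ranks first — the recovery property the acceptance suite checks over 20
seeds.

## Numerical and design choices

* **Problem sizes.** The test and acceptance suites run the reference
  architecture (2 × 100 units, batch 64) on 160-sample scenes at 20–25
  epochs, and property loops at 1,000 random cases — sizes chosen so the
  whole suite completes in minutes while leaving the statistical properties
  clearly resolved. The 700-epoch, 15,709-sample configuration is the
  package default for real runs.
* **Tolerances.** Denominator guards at 1e−9 (reflectance scale);
  correlation tie-breaks at 1e−15; gradient checks at 1e−5 relative.
* **Determinism.** One global pipeline seed derives per-stage seeds by fixed
  offsets (simulation +0, split +100, LSTM +200, importance +300), so any
  stage can be reproduced in isolation. Generators consume fixed offsets of
  the scene seed likewise.
* **Degenerate inputs.** Flat yield fields map to the range midpoint;
  constant index columns flag their correlation as missing; empty
  significance slots warn; fully-cloudy seasons and unsplittable sample
  counts are hard errors.
* **Raster export.** Yield maps are written as 32-bit float TIFF plus an
  ESRI world file and a JSON sidecar carrying value scaling, the nodata
  code (0) and the affine georeference; `read_yield_map()` inverts the
  packing to float32 precision. Masked cells are stored as the declared
  nodata value.

## Known limitations

* The LSTM trainer is plain R; it is fast enough for field-campaign scales
  (thousands of samples) but not for regional mosaics.
* The generator's planted signals are additive and pairwise; it cannot
  express multi-band interactions, so the screening's behaviour under
  collinear broadband structure is exercised only weakly.
* Reported headline accuracies from the original field campaign depend on
  unreleased data and are not reproduced here; the package's claims are the
  structural and statistical properties its own tests compute.
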