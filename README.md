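# wheatyield

Grid-scale winter wheat yield estimation from satellite reflectance, as a
tested R pipeline. The package is aimed at agricultural remote-sensing
researchers who want the full analysis — data model, feature construction,
band screening, sequence and baseline regressors, evaluation — as reusable,
reproducible code rather than a one-off script.

## What it computes

Given per-cell yields *y* (t/ha, on a 5 m grid) and reflectance, the
pipeline builds two kinds of model input:

* **Multispectral:** four vegetation indices per month over the Oct–Jun
  season —

  EVI = 2.5 (B8 − B4)/(B8 + 6 B4 − 7.5 B2 + 1),  SR = B8/B4,
  NDWI = (B8 − B11)/(B8 + B11),
  REP = 705 + 35 (0.5 (B4 + B7) − B5)/(B6 − B5) nm

  — after discarding scenes with cloud cover > 30% and averaging within
  months, giving a 4 × 9 matrix per sample (flattened to 1 × 36 for
  non-sequence models).

* **Hyperspectral:** for 163-band spectra *R*, every two-band index
  SSI = Rᵢ − Rⱼ, RSI = Rᵢ/Rⱼ, NDSI = (Rᵢ − Rⱼ)/(Rᵢ + Rⱼ) is screened
  against yield over all 13,203 unordered band pairs (ordered for the
  asymmetric RSI); the extreme significantly correlated pairs (p < 0.001)
  define three custom indices, evaluated on four acquisition dates
  (3 × 4 input).

Four regressors map features to yield: a two-layer, 100-unit **LSTM**
(dropout 0.3, L2, Adam at lr 0.001, batch 64, 700 epochs) consuming the
monthly sequence, and **RF** (150 trees, OOB error), **GBDT** (1250 rounds,
subsample 0.6, lr 0.1) and **SVR** (RBF, C = 1e5, γ = 0.5) on the flattened
vector. Models are compared by MAE, RMSE and R², and interpreted by
permutation feature importance (shuffle one index's whole trajectory,
re-predict without retraining, rank by loss increase).

Because the original field measurements are not publicly deposited, the
package ships a synthetic scene generator (yield grids with the
centre-high/edge-low pattern, phenology-driven band time series, spectra
with planted informative band pairs, a management-factor experiment) whose
defaults match the campaign's published characteristics; every stage is
tested against it.

## Worked example

```r
library(wheatyield)

cfg <- pipeline_config(scene = scene_config(n_rows = 20, n_cols = 20),
                       lstm = lstm_config(epochs = 60), seed = 42)
res <- run_full_pipeline(cfg, "multispectral", "runs/demo")
print(res$metrics, digits = 3)
#>   model    mae  rmse    r2  m
#> 1  LSTM 0.0809 0.117 0.991 40
#> 2    RF 0.0725 0.137 0.988 40
#> 3  GBDT 0.0736 0.125 0.990 40
#> 4   SVR 0.6293 0.908 0.476 40

print(res$importance$importance, digits = 3)
#>   feature   loss rank
#> 1      SR 0.4816    1
#> 2    NDWI 0.4387    2
#> 3     EVI 0.1933    3
#> 4     REP 0.0141    4
```

The metrics table is the held-out 10% test split (m = 40 of 400 cells):
the sequence model and the tree ensembles track the synthetic yield surface
closely, while SVR — whose sharp RBF kernel cannot pool across the
36-dimensional flattened input — trails, mirroring the ordering reported
for the field data. The importance table says the greenness ratio SR
carries the most yield information, followed by the water index NDWI;
shuffling REP barely moves the loss.

Band screening on a generated spectra table:

```r
tb <- simulate_hyperspectral_samples(config = scene_config(seed = 42))
select_bands(tb)$NDSI
#> <selection_result> NDSI (p < 0.001)
#>   positive: 1376-1896 nm, r = 0.9609
#>   negative: 516-1376 nm, r = -0.9483
```

The selected extremes land on the planted SWIR (positive) and visible/NIR
(negative) band pairs — the sign structure the screening is designed to
recover.

A command-line wrapper ships in `inst/cli/wheatyield.R`:

```sh
Rscript inst/cli/wheatyield.R simulate --out runs/scene --seed 3
Rscript inst/cli/wheatyield.R select-bands --in runs/scene/hyperspectral.csv --out runs/sel
Rscript inst/cli/wheatyield.R run-all --config config.yaml --out runs/full --seed 3
```

## Package layout

- `R/` — generators, indices/compositing, band selection, LSTM (cell,
  BPTT trainer), baselines, metrics/importance, raster and CSV IO,
  pipeline and CLI.
- `vignettes/methods.Rmd` — the model, its assumptions, what the generator
  does and does not emulate, and every open design choice with its
  rationale.
- `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code).
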