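# canopyphot

Estimating and mapping leaf photosynthetic capacity from five-band UAV
multispectral imagery.

## The problem

The photosynthetic capacity of a C3 crop canopy is summarised by two
parameters of the Farquhar–von Caemmerer–Berry (FvCB) model: the maximum
Rubisco carboxylation rate **Vcmax** and the maximum electron transport rate
**Jmax**, both in µmol m⁻² s⁻¹ referenced to 25 °C. They are measured by
fitting A–Ci gas-exchange curves,

```
A = min(Ac, Aj) − Rd
Ac = Vcmax · (Ci − Γ*) / (Ci + Kc · (1 + O/Ko))
Aj = J · (Ci − Γ*) / (4·Ci + 8·Γ*),   θJ² − (αQ + Jmax)J + αQ·Jmax = 0
```

with all rates Arrhenius-scaled between leaf temperature and 25 °C. Gas
exchange is accurate but slow — minutes per leaf — which rules it out as a
phenotyping screen. Because leaf nitrogen and chlorophyll drive both the
FvCB parameters and canopy reflectance in the visible/red-edge region,
broad-band spectral indices from an inexpensive five-band (blue, green, red,
red-edge, NIR) drone camera can stand in for the measurement: an index bank
is computed from soil- and shadow-masked canopy reflectance, LASSO picks the
informative indices, and a partial least squares regression (PLSR) with
cross-validated component count predicts the trait — per sample for model
building, per pixel for field maps.

`canopyphot` implements that whole chain for researchers and breeders
working with nitrogen-gradient or multi-variety field trials:

* **FvCB engine** — forward simulation of rapid A–Ci ramps
  (30 → 1830 µmol mol⁻¹ at 200 µmol mol⁻¹ min⁻¹, one record per 5 s = 108
  records) and bounded Levenberg–Marquardt fitting of (Vcmax25, Jmax25,
  Rd25) with multi-start.
* **Imaging** — calibration-panel radiometric correction, excess-green
  masking (ExG = 2ρG − ρR − ρB > 0.07) of soil and leaf shadow, ROI mean
  reflectance, GSD geometry.
* **Index registry** — NDVI, NDRE, SCCCI = NDRE/NDVI, CVI, chlorophyll
  indices, RGB indices, raw bands and reciprocals (30+ formulas), guarded
  against division by zero and user-extensible.
* **Modeling** — seeded 2:1 calibration/validation split, univariate index
  baselines, LASSO selection with 10-fold cross-validated λ (via glmnet),
  NIPALS PLS1 with cross-validated components, VIP scores, and the standard
  metric set (R², |r|, RMSE, bias, rRMSE).
* **Mapping** — per-pixel trait rasters with per-plot summaries.
* **Synthetic fields** — a seeded generator of nitrogen-gradient scenes and
  forward-simulated A–Ci curves with known truth, so the full pipeline is
  testable without any field campaign.

## Worked example

```r
library(canopyphot)

## one rapid A-Ci curve with 0.5 umol m-2 s-1 instrument noise, then refit
crv <- simulate_aci(c(vcmax25 = 82, jmax25 = 156, rd25 = 1.1),
                    noise_sd = 0.5, seed = 7)
fit_aci(crv)
#> FvCB A-Ci fit
#>   Vcmax25 = 83.20, Jmax25 = 155.99, Rd25 = 1.072 umol m-2 s-1
#>   RMSE = 0.465 over 108 points (20 Rubisco-limited), converged

## a 210-plant synthetic nitrogen trial: scene + gas exchange + indices
truth   <- generate_truth(3, 14, seed = 42)        # 5 N levels x 3 plots x 14
layout  <- field_layout(truth)
scene   <- render_scene(layout, truth, seed = 7943)
samples <- extract_trait_samples(truth, layout, scene, pipeline_config(seed = 42))

## 2:1 split, LASSO + PLSR for Vcmax, validation metrics
sp  <- split_dataset(samples, ratio = 2/3, seed = 42)
idx <- intersect(index_registry(include_stubs = FALSE)$name, colnames(samples))
tm  <- fit_trait_model(sp$calibration[, idx], sp$calibration$vcmax25,
                       folds = 10, seed = 42, trait = "vcmax25")
tm
#> LASSO selection: 12 indices at lambda = 0.0045489
#>   SCCCI, CVI, CI_RE, GBRI, IKAW, ExG, SIPI, G, RE, NIR, 1/B, 1/RE
#> PLSR trait model [vcmax25]: 12 indices, 8 component(s)
#>   calibration R2 = 0.924, RMSE = 5.662

evaluate_predictions(predict(tm, sp$validation[, idx]), sp$validation$vcmax25)
#>          r2         r     rmse       bias rrmse_percent  n
#> 1 0.9097461 0.9549413 6.130094 -0.1895223      8.528541 70

## per-pixel Vcmax map and per-plot means
map_traits(scene, tm)
#> trait_map [vcmax25]: 9261 valid px, range 9.26..173.06, mean 73.27
```

The validation block reads: the model explains 91 % of the Vcmax variance in
the 70 held-out plants, with a 6.1 µmol m⁻² s⁻¹ RMSE (8.5 % of the mean) and
negligible bias. Plot-level map means rise monotonically with the nitrogen
treatment, as the generator's truth says they must.

A command-line wrapper with `simulate`, `fit-aci`, `extract`, `train`,
`evaluate`, `map` and `run` subcommands ships in `inst/cli/canopyphot.R`;
`run_pipeline()` executes every stage and writes a hashed artifact manifest.

## Documentation

The methods vignette (`vignettes/canopy-photosynthesis.Rmd`) describes the
model, the synthetic-field generator and its assumptions, the numerical
choices in the optimiser and the cross-validation, and what the synthetic
benchmarks do and do not say about real field data.
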