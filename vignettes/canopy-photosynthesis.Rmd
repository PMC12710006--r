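---
title: "Estimating canopy photosynthetic traits from five-band imagery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating canopy photosynthetic traits from five-band imagery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`canopyphot` estimates the two FvCB parameters that summarise C3
photosynthetic capacity — the maximum Rubisco carboxylation rate Vcmax and
the maximum electron transport rate Jmax, both at a 25 °C reference — first
from gas exchange (the ground truth) and then from five-band canopy
reflectance (the scalable proxy). This vignette is the package's own account
of the models involved, the defaults chosen where the literature leaves
latitude, and what the synthetic benchmarks do and do not demonstrate.

## 1. The FvCB engine

Net assimilation is the minimum of the Rubisco-limited and
RuBP-regeneration-limited rates, less day respiration:

$$A = \min(A_c, A_j) - R_d, \qquad
A_c = \frac{V_{cmax}(C_i - \Gamma^*)}{C_i + K_c(1 + O/K_o)}, \qquad
A_j = \frac{J(C_i - \Gamma^*)}{4C_i + 8\Gamma^*},$$

with $J$ the lower root of $\theta J^2 - (\alpha Q + J_{max})J + \alpha Q
J_{max} = 0$. Every rate is Arrhenius-scaled between leaf temperature and
25 °C: $k(T) = k_{25}\exp[E_a(T - 298.15)/(298.15\,R\,T)]$.

Fixed kinetics default to the Bernacchi-type in vivo set that the standard
A–Ci fitting tools use: $\Gamma^*_{25} = 42.75$, $K_{c,25} = 404.9$
µmol mol⁻¹, $K_{o,25} = 278.4$, $O = 210$ mmol mol⁻¹, with activation
energies (J mol⁻¹) 37 830, 79 430, 36 380 for $\Gamma^*$, $K_c$, $K_o$ and
65 330, 43 540, 46 390 for $V_{cmax}$, $J_{max}$, $R_d$. The light response
uses $\theta = 0.85$, $\alpha = 0.24$ and $Q = 1500$ µmol m⁻² s⁻¹, the
acclimation irradiance of the rapid-curve protocol.

Design choices where the convention is genuinely open:

* **Hard minimum of $A_c$ and $A_j$.** Some tools smooth the transition
  with a hyperbolic minimum; the smoothing parameter is a free constant
  with no consensus value, so we keep the plain minimum, which is already
  continuous at the crossover ($A_c = A_j$ there).
* **$R_d$ is fitted, bounded to [0, 10] µmol m⁻² s⁻¹** rather than fixed,
  since rapid ramps carry enough low-$C_i$ information to identify it.
* **No TPU limitation.** Triose-phosphate limitation only binds at high
  $C_i$ and low temperature; adding a third regime would add a parameter
  the 108-point ramp cannot reliably separate.

### Fitting

`fit_aci()` minimises $\sum_i (A_i - \hat A(C_{i,i}))^2$ over (Vcmax25,
Jmax25, Rd25) with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
`ftol = ptol = 1e-10`, up to 500 iterations), started from three documented
points — (50, 100, 1), (100, 190, 2), (20, 40, 0.5) — spanning low to high
capacity; the best sum of squares wins. The multi-start guards against the
kink the `min()` puts into the residual surface. The curve's leaf
temperature enters through the forward model, so reported parameters are
already at 25 °C. On noise-free forward-simulated ramps the round trip
recovers the generating parameters to ~1e-15 relative; under 0.5
µmol m⁻² s⁻¹ Gaussian instrument noise the median relative bias of Vcmax25
over 200 replicate fits is below 0.2 %.

Per-plant traits are the arithmetic mean of the (converged) leaf-level
fits, mirroring the practice of averaging the measured top leaves.

## 2. Imaging

Radiometric calibration is the one-point empirical line: per band, gain =
nominal panel reflectance (0.5) / mean panel digital number, applied
multiplicatively and clipped to [0, 1.5] with the clip count recorded.
Scale equivariance (same gain for raw and panel) is tested.

Soil and leaf shadow are removed with the excess green index
ExG $= 2\rho_G - \rho_R - \rho_B$, thresholded strictly at 0.07 — the
operational value for suppressing background interference. ExG is computed
on calibrated band reflectance, not on chromatic coordinates; a
chromatic-coordinate ExG variant exists in the literature, and users can
register it as an additional index if their sensor calibration warrants it.
ROI reflectance is the per-band arithmetic mean over masked valid pixels.

Ground sample distance follows the pinhole relation gsd = altitude × pixel
pitch / focal length: 30 m × 3.75 µm / 5.4 mm ≈ 0.0208 m, i.e. 2 cm.

## 3. The spectral index registry

All indices named in the main broad-band literature set are registered as
self-contained expressions over $\{\rho_B, \rho_G, \rho_R, \rho_{RE},
\rho_{NIR}\}$ — 32 computable entries including NDVI, NDRE, their ratio
SCCCI, CVI $= \rho_{NIR}\rho_R/\rho_G^2$, the chlorophyll indices, the RGB
set, raw bands, reciprocals, and the chromatic coordinates g and b. Five
names that appear in published index collections but whose exact formulas
we could not verify (IPCA, CI2, WI, NDI, VIre) ship as *stubs*: they are
listed, but computing them raises an "unregistered formula" error until the
user supplies a definition — we never guess a formula. GBRI is defined as
$\rho_G/\rho_B$ (green over blue); the direction is documented and
trivially invertible if a user's convention differs.

Guard violations (zero denominators, negative square-root arguments)
return flagged missing values rather than errors, so batch index tables
survive odd pixels; downstream modeling drops flagged rows.

The SCCCI deserves its own note: NDRE responds to foliar pigments, LAI and
soil background while NDVI responds mainly to LAI and soil background, so
their ratio approximately cancels the structural terms and isolates the
pigment signal. Under the package's own Beer-law canopy model this is an
assertable property — over LAI ∈ [1, 4] at fixed chlorophyll, the relative
range of SCCCI is less than half that of NDRE — and it is tested.

## 4. Trait modeling

Samples are split 2:1 into calibration and validation by a seeded shuffle
(`round(N·2/3)` calibration; 204 → 136 + 68). The split is unstratified:
nothing in the protocol mandates stratification, and an unstratified seeded
shuffle is the simplest reproducible choice.

**LASSO selection** standardises the index columns and minimises CV mean
squared error along a geometric penalty path from $\lambda_{max}$ (smallest
penalty zeroing all coefficients) down four decades, 10-fold, seeded. Ties
are broken toward the larger penalty — the sparser model. Selection is the
set of nonzero coefficients at $\lambda^*$. On an orthonormal design the
coefficients equal soft-thresholded OLS, which the tests verify to 1e-6
against the closed form.

**PLSR** is one-response NIPALS on centred, unit-variance predictors and a
centred response, implemented in-package (the component internals are
needed for VIP anyway) and cross-checked in the tests against an
independent implementation and against OLS at full rank. The component
count minimises seeded 10-fold CV RMSE over 1..min(p, n−1), with fold-local
centring/scaling and ties broken toward fewer components. If LASSO keeps
fewer than two indices, the selection is topped up with the
best-correlated indices so the PLS stage is well-posed.

**VIP scores** use $VIP_j = \sqrt{p\sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a
SS_a}$ with $SS_a = q_a^2 t_a^\top t_a$; the mean squared VIP is exactly 1,
and indices above 1 are flagged influential.

Metric conventions, fixed once: bias = mean(predicted − observed); rRMSE =
100·RMSE / mean(observed) on the evaluation set; r is the absolute Pearson
correlation.

## 5. Mapping

`map_traits()` predicts per pixel, not from ROI means: each sunlit
vegetation pixel (ExG > 0.07) gets its own index vector and model
prediction, matching how trait maps are actually produced. Predictions are
deliberately not clipped to physiological ranges — single-index maps in
particular can swing wide, and clipping would hide that model behaviour;
out-of-range pixels can be counted via `range_flag`. For linear models the
map of a spectrally uniform ROI equals the tabular prediction exactly; for
ratio indices pixel-level and ROI-mean predictions differ by Jensen-type
gaps, which is documented behaviour rather than a defect.

## 6. The synthetic field generator

The generator encodes the causal structure the analysis assumes: a latent
leaf nitrogen per area (g m⁻²) whose treatment mean rises linearly from
1.0 at 0 kg/hm² to 2.2 at 520 kg/hm² across the five nitrogen levels
N0–N4, driving chlorophyll (28 µg cm⁻² per g m⁻²), Vcmax25 (45
µmol m⁻² s⁻¹ per g m⁻²), Jmax25 (1.9 × Vcmax25, inside the physiological
1.2–2.5 band), Rd25 (1.5 % of Vcmax25) and LAI (1.2 per g m⁻²), each with
mean-corrected multiplicative lognormal noise (sdlog 0.05–0.10). These
magnitudes put Vcmax in the 30–130 µmol m⁻² s⁻¹ range typical of
fertilised herbaceous canopies; the Jmax:Vcmax ratio of 1.9 keeps both
limitations active along the CO2 ramp. The ratio's distribution is our
choice, not a literature-constrained value.

Scene reflectance uses a Beer-law two-stream caricature:
$\rho_b = \rho_{soil,b}e^{-k_b L} + \rho_{leaf,b}(Cab)(1 - e^{-k_b L})$,
with leaf reflectance decaying exponentially in chlorophyll in the
visible/red-edge bands (red edge most sensitive), a pigment-insensitive
NIR leaf reflectance of 0.45, a flat 0.20 soil spectrum (so soil ExG is 0
and $\rho_{NIR} \approx \rho_R$), per-band extinction decreasing toward the
NIR, band-neutral lognormal pixel brightness, small additive sensor noise
(sd 0.004), and a seeded 10 % of canopy pixels darkened by a uniform ×0.3
across all bands to emulate shadow. This deliberately encodes the
LAI/soil confounding that motivates ratio indices like SCCCI, without a
full radiative-transfer model.

One semantic worth stating plainly: the generator's returned vegetation
mask marks *sunlit* canopy — shadowed canopy pixels are carried in a
separate mask. The ExG threshold step is designed to remove soil *and*
leaf shadow, and a band-neutral ×0.3 darkening scales ExG by 0.3, which
pushes any plausible canopy pixel (ExG ≲ 0.2) below the 0.07 threshold.
So the correct segmentation target — and the one the F1 benchmark uses —
is the sunlit-canopy mask.

What the generator does **not** emulate: bidirectional reflectance and
sun-angle effects, mixed soil/canopy edge pixels, within-plant chlorophyll
gradients, registration error between bands, atmospheric variation between
flights, and any decoupling of nitrogen from chlorophyll (in the generator
their correlation is, by construction, near 1). Passing the synthetic
benchmarks therefore demonstrates that the pipeline's machinery is
correct — masks recover known truth, estimators recover generating
parameters, the two-stage model extracts a signal that is genuinely there —
not that any particular accuracy will be achieved on real fields, where
the index–trait correlation is much weaker. Indeed the synthetic validation
R² (~0.9) is *higher* than is realistic precisely because the generator's
latent-nitrogen pathway is clean; and because single red-edge indices are
already near-optimal under this generator, the LASSO+PLSR improvement over
the best univariate baseline is directionally reproducible but small, and
on some random splits the baseline ties it.

## 7. Problem sizes and runtime choices

The default synthetic trial is 5 treatments × 3 replicate plots × 14
plants = 210 plants on a 284 × 168 pixel scene at 2 cm GSD — large enough
for a 140/70 split with 10-fold CV and stable per-plot statistics, small
enough that the full pipeline (210 simulated ramps, 210 FvCB fits, LASSO,
PLSR, two maps) runs in a few seconds on one core. The acceptance script
uses 200 replicate noisy fits for the bias estimate and a 3 × 3 × 2
parameter grid for the round trip; both sizes give Monte-Carlo error well
inside the tolerances they are checked against.

## 8. Known limitations

* Rasters are plain multi-page TIFF plus a JSON sidecar (gsd, scale); no
  CRS/geotransform handling, so outputs are pixel-registered, not
  geo-registered.
* The one-point panel calibration has no dark-current offset term.
* PLS1 only (one response at a time); no joint Vcmax/Jmax model.
* No mesophyll conductance, stomatal coupling or energy balance in the
  FvCB engine; Ci is taken as given by the gas-exchange system.
* The five supplementary-only index stubs remain stubs until a user
  registers formulas.
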