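---
title: "Methods: plot-level hyperspectral phenotyping of photosynthetic traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plot-level hyperspectral phenotyping of photosynthetic traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plotspectra)
```

## The problem this package addresses

Photosynthetic capacity is conventionally measured leaf by leaf with
infra-red gas analyzers — slow, destructive of field time, and hard to scale
to breeding trials with hundreds of plots. Proximal hyperspectral imaging
offers an alternative: a push-broom camera pair scans a ~2 m x 2 m plot in
under a minute, and a statistical model maps the plot's sunlit-leaf
reflectance spectrum to traits such as the maximum Rubisco carboxylation
rate (Vc,max), the electron transport rate at a reference irradiance of
1800 umol m-2 s-1 (J1800), chlorophyll content, the Chl a:b ratio, carbon
and nitrogen content, light-saturated photosynthesis (Pmax) and the
apparent quantum yield of CO2 fixation (phiCO2).

`plotspectra` implements that pipeline end to end:

1. **Radiometry** — ENVI hypercube I/O and conversion of raw digital
   numbers to absolute radiance via per-band (or per-spatial-channel) gain,
   offset, dark frame and integration time.
2. **Scene understanding** — K-means clustering of per-pixel radiance into
   six material classes, then physics-based semantic labeling (white
   reference panel, sunlit and shaded leaves, soil, platform shadow,
   non-biological matter).
3. **Reflectance** — per-pixel conversion against the in-scene panel,
   aggregation to a plot mean +/- SD, joining of the two camera ranges,
   Savitzky-Golay smoothing and removal of noisy/water-absorption bands.
4. **Leaf-clip QC** — splice correction and replicate filtering for
   spectroradiometer spectra used in leaf-level models.
5. **PLSR trait models** — NIPALS PLS1 with leave-one-out PRESS component
   selection, 1000x random-resampling validation, and VIP diagnostics.
6. **Physiological ground truth** — FvCB A/Ci curve fitting (Vc,max, J1800)
   with a temperature-constrained mesophyll conductance, and
   non-rectangular hyperbola light-response fitting (Pmax, phi, theta, Rd,
   phiCO2).
7. **Synthetic generators** — scenes, trait-coupled spectra and
   gas-exchange curves with known ground truth, so every stage is testable
   at desk scale.

## Radiometric model

Raw digital numbers are converted to radiance as

$$L = \frac{(DN - dark)\cdot gain}{t_{int}} + offset,$$

clipped below at zero. The affine form reduces to the identity under unit
parameters, makes calibration linear in DN (so plot means commute with
calibration), and accepts either per-band or per-band-per-spatial-channel
gain/dark shapes — manufacturer calibration files come in both layouts.
Raw DN cubes are stored as unsigned 16-bit integers, calibrated cubes as
floats; the on-disk dialect is a classic ENVI text header next to a flat
binary (BIL by default, the push-broom native order).

## Scene segmentation and labeling

Per-pixel spectra are clustered with Lloyd's K-means (Euclidean metric,
k-means++ starts, best of `n_init = 10` restarts by within-cluster sum of
squares, fixed seed recorded in the output). `k = 6` matches the six
materials a plot scene contains; scenes lacking a class can use a smaller
`k`.

Cluster naming is intentionally simple physics rather than learned rules:

- the **panel** is the cluster with the highest mean broadband radiance (a
  near-unity-reflectance reference under full sun dominates everything);
- clusters whose centroid vegetation index `(R800 - R670)/(R800 + R670)`
  exceeds 0.5 are **vegetation** — the red-edge contrast no other scene
  material shows; among them, brightness above the vegetation median
  separates **sunlit** from **shaded** leaves (illumination cancels in the
  index but not in brightness);
- of the remaining clusters the darkest is **platform shadow**; index
  below 0.3 marks **soil**, anything else **non-biological matter**.

The thresholds (0.5 / 0.3) are configuration-exposed. Clustering operates
on radiance, before reflectance conversion, mirroring the acquisition
pipeline's phase order. The index needs red and NIR bands that only the
VNIR camera has, so when both cameras are processed the class map is
segmented on the VNIR cube and reused for the co-registered NIR cube.

## Reflectance and the plot spectrum

Reflectance uses the in-scene white panel:
$$R = \frac{S_{sunlit}}{S_{ref}} \cdot R_{ref},$$
with \(R_{ref}\) the lab-calibrated panel reflectance (0.99 by default).
The ratio removes the illumination, so reflectance is invariant to global
brightness changes — a property the tests assert directly. Sunlit-leaf
pixels are averaged per band (population SD reported alongside), the two
cameras are joined at a 900 nm crossover (VNIR below, NIR at/above, no
resampling — the union grid keeps each camera's native 2.1 / 4.9 nm step),
the joined mean spectrum is smoothed (Savitzky-Golay, window 11, order 2),
and bands below 450 nm, above 1700 nm and inside 1313-1440 nm (atmospheric
water absorption) are removed.

Two deliberate design choices:

- **Smoothing acts on the plot mean, after aggregation.** Averaging and
  the linear filter commute, so the plot mean is identical to per-pixel
  smoothing at a fraction of the cost; a flag restores per-pixel mode via
  the lower-level functions. Smoothing precedes masking so the filter
  window never straddles the deleted water region.
- **Edge handling by truncated-window fits.** The filter solves the local
  least-squares polynomial on whatever window actually exists at the
  spectrum ends, so polynomials of degree <= 2 pass through unchanged
  everywhere and no padding artifacts appear.

## Leaf-clip spectra QC

Spectroradiometer detectors meet at ~1000 and ~1800 nm; heat drift shifts
the outer detectors relative to the central NIR detector. The splice
correction adds a constant to each outer segment so its junction-adjacent
band matches the linear extrapolation of the five nearest reference-side
bands; the correction is idempotent and leaves the central segment
untouched.

Replicate QC is a single pass: (a) replicates with reflectance above 0.10
at 450 nm are flagged (leaf-clip seal failure — the paper-level protocol
gives no number, so the threshold is configuration-exposed); (b) the "2%
deviation" rule is interpreted as a band-averaged mean absolute deviation
above 0.02 reflectance units from the replicate mean — an absolute
criterion, because a relative 2% rule explodes in the visible trough where
reflectance is ~0.03; (c) a leaf with fewer than four surviving replicates
is rejected. QC only flags; spectra are never modified.

## PLSR with PRESS selection and VIP

The trait model is PLS1 by NIPALS on mean-centered, unscaled data
(reflectance bands share units; this matches the long-standing default of
the R `pls` ecosystem used in field spectroscopy). For each candidate
component count `a = 1..max_lv` (default cap `min(15, n - 2)`), the
leave-one-out PRESS is computed with every fold re-centered and refit; the
selected count minimizes the PRESS RMSE, ties broken toward fewer
components. Predictions use the composed per-band coefficient vector
\(b = W (P^\top W)^{-1} q\).

Validation repeats 1000 random train/test splits (default 20% holdout —
the resampling fraction is not standardized in the field, so it is
configuration-exposed). Each training fold re-runs the full component
selection, so no information leaks from the full-data fit. Each sample's
reported prediction is the mean over the resamples in which it was held
out; `r2_cv`, `rmse`, `bias` are computed from those mean predictions, and
`rmse_pct = 100 * rmse / (max(y) - min(y))` — the range-normalized
convention that reproduces the published per-trait RMSE% values from
published RMSE and trait ranges. `r2_train` comes from the full-data fit
at the selected component count.

Variable importance in projection is
$$VIP_j = \sqrt{p \cdot \frac{\sum_a SSY_a (w_{ja}/\lVert w_a \rVert)^2}
{\sum_a SSY_a}}, \qquad SSY_a = q_a^2\, t_a^\top t_a,$$
which satisfies \(\sum_j VIP_j^2 = p\) identically — asserted on every fit.

## Gas-exchange ground truth

**A/Ci.** Net assimilation follows the Farquhar-von Caemmerer-Berry
model, `A = min(Ac, Aj) - Rd`, with the chloroplastic CO2
`Cc = Ci - A/gm` solved self-consistently (Ethier-type quadratic per
limitation). Mesophyll conductance is not fitted: it is constrained by the
linear temperature relation `gm = -0.44 + 0.058 T` (mol m-2 s-1 bar-1),
evaluated at the curve's leaf temperature — `gm(25) = 1.01`. Kinetic
constants (Kc, Ko, Gamma*) and their Arrhenius temperature responses are
the standard tobacco-derived values shipped in an editable constants
object, since any A/Ci fit must state them somewhere auditable. Fitting
enumerates the Ci cutover between Rubisco- and RuBP-limited regions
(at least four low-Ci points must be available to identify Vc,max),
solves a bounded least-squares problem per assignment
(Levenberg-Marquardt), and keeps the assignment with minimum RSS, ties
toward more Rubisco-limited points. J1800 is reported only when at least
two points are RuBP-limited — low-Rubisco germplasm can stay
Rubisco-limited across the whole CO2 range, in which case the electron
transport rate is honestly unidentifiable and flagged `NA`. TPU limitation
is not modeled, Rd is fitted (bounded at zero), and no temperature
normalization to 25 C is applied — models are built at ambient
temperature.

**A/Q.** Light-response curves are corrected to absorbed irradiance
`Ia = Q * absorptance` and fitted with the non-rectangular hyperbola
$$A(I_a) = \frac{\phi I_a + P_{max} - \sqrt{(\phi I_a + P_{max})^2 -
4\phi I_a \theta P_{max}}}{2\theta} - R_d$$
by bounded least squares (theta in (0.01, 1], phi in (0.01, 0.125], Rd >=
0), initialized from the data (low-light slope, dark point, maximum).
phiCO2 is estimated separately as the free-intercept OLS slope of A on Ia
below 150 umol m-2 s-1; phi in the hyperbola is freely fitted rather than
pinned to that slope, and the slope is always at or below the fitted phi.
As theta tends to 0 the model reduces to the rectangular hyperbola; the
implementation switches to that closed form below theta = 1e-9 (the exact
formula's residual term scales linearly in theta, ~4e-6 at theta = 1e-6,
so the forms agree to 1e-6 from about theta = 1e-7 downward).

## What the synthetic generators emulate — and what they do not

`simulate_scene` renders each pixel as
`illumination(class) * endmember_reflectance(class) * (1 + e)`, with
multiplicative Gaussian noise (detector shot-noise-like) and panel pixels
always sunlit. Shaded pixels share the leaf endmember under a lower
illumination scalar — the simplest mechanism that makes "sunlit vs
shaded" a brightness distinction K-means can separate. Default
conditions: class fractions 0.40/0.20/0.20/0.10/0.05/0.05 (sunlit leaf /
shaded leaf / soil / panel / shadow / non-biological), illumination
contrast 1000:300, camera grids 400-900 nm at 2.1 nm (240 bands) and
900-1800 nm at 4.9 nm (184 bands). The default non-biological endmember
carries a moderate red/NIR contrast (vegetation index ~0.38,
senesced-material-like) so the labeling rules can distinguish it from
soil; a spectrally flat gray object would be indistinguishable from soil
under the index-threshold rule. The generators do **not** model canopy
radiative transfer, BRDF/anisotropy, leaf-angle effects or within-canopy
scattering — passing tests demonstrate the pipeline's internal
correctness, not robustness to those field effects.

`simulate_trait_dataset` draws plot spectra as a mean vegetation spectrum
plus low-order B-spline bumps (default 25 basis functions over the grid,
~18 nm feature scale — comparable to pigment absorption features) and a
multiplicative brightness factor, producing the strongly collinear
predictor sets PLSR exists for while keeping band-localized couplings
recoverable; traits are linear in the spectra with additive noise, and
`r2_true` calibrates the noise so the true signal explains a chosen
variance share. `simulate_gas_exchange` forward-simulates both curve
types on the standard measurement step sequences (CO2: 400, 200, 50, 100,
300, 400, 600, 900, 1200, 1500, 1800, 2000 umol mol-1; light: 2000, 1800,
1400, 1000, 600, 400, 200, 150, 100, 75, 50, 0 umol m-2 s-1).

## Numerical choices and degenerate inputs

- K-means on fewer than `k` distinct spectra raises a degenerate-clustering
  error; brightness ties in labeling break toward the lower cluster id.
- The PLS core stops extracting components when the residual covariance
  vanishes (tolerance 1e-12); deeper candidate ranks reuse the deepest
  available prediction, so PRESS plateaus and the first-minimum rule picks
  the true rank on exact low-rank data.
- A constant trait vector, fewer than four samples, or missing values are
  hard errors, not warnings.
- `gm_at_temperature` warns outside 5-45 C and clips at 0.05 mol m-2 s-1
  bar-1 where the line would turn non-physical.
- Non-positive panel radiance at any band is an error naming the band —
  silent division is never attempted.

## Problem sizes used in the shipped checks

The test-suite and acceptance script exercise: 60x60 (noiseless) and
160x160 (1% noise, >= 10^4 sunlit pixels) scenes for reflectance
recovery; ten 100x100 scenes for segmentation agreement; n = 200 plots x
216 retained VNIR bands with 1000 resamples for PLSR validation; and the
full printed step grids for the gas-exchange fitters. These sizes were
chosen as the smallest at which the statistical assertions (CLT-scale
error bounds, 99% cluster agreement, CV R2 within 0.1 of the designed
0.9) are stable across seeds.

## Known limitations

- Semantic labeling assumes a panel in view and at least one vegetation
  cluster; non-vegetated scenes error by design.
- The two cameras are assumed co-registered when a class map is shared;
  plots imaged with different spatial footprints must be processed
  per-camera and joined at the plot-mean level.
- The FvCB constants ship as tobacco-style defaults; other species need an
  edited constants object.
- No atmospheric correction beyond band deletion, no temperature
  normalization of spectra or traits, and no TPU-limited FvCB state.
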