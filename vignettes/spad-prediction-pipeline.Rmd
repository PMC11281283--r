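---
title: "Predicting winter wheat SPAD from simulated UAV multispectral imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting winter wheat SPAD from simulated UAV multispectral imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

SPAD readings are a unitless proxy for leaf chlorophyll content, routinely
measured on wheat flag leaves with a transmittance meter. Mapping them from
UAV multispectral imagery replaces slow leaf-by-leaf field work with a single
flight. Two practical questions dominate such campaigns: how high can the
UAV fly (coarser ground sampling distance, larger coverage) before
prediction degrades, and which predictor variables -- spectral vegetation
indices (VIs), gray-level co-occurrence texture indices (TIs), or discrete
wavelet features (DWT) -- carry the signal.

`spaduav` implements that analysis as a reusable, fully testable pipeline.
Because raw field imagery of this kind is rarely public, the package ships a
first-class synthetic-scene generator with a known SPAD-to-reflectance
forward model, so every stage from feature extraction to model evaluation
can be exercised end to end with ground truth in hand.

## The synthetic field

`generate_design()` reproduces a 72-plot split-plot layout: Experiment 1
crosses four varieties with four nitrogen rates (0/150/240/330 kg/ha) in
three replicates (48 plots); Experiment 2 crosses two varieties with four
fertilizer application methods at 240 kg/ha (24 plots). Plots are 3 m x 4 m
(12 m^2) with 25 cm row spacing on a 12 x 6 grid with 0.5 m alleys. The seed
shuffles which treatment lands where; the factorial structure is invariant.

True plot SPAD follows
`mu0 + variety offset + f(N) + method offset + N(0, sigma_plot)`, truncated
to the meter range 0--99.9. The nitrogen response
`f(N) = n_span N / (N + n_half)` is monotone and saturating. The defaults
(`mu0 = 45`, `n_span = 15.4`, `n_half = 180`, `sigma_plot = 1.5`) put plot
means around 45--55 SPAD with roughly a 10-unit span across nitrogen rates
-- values a field agronomist would call ordinary for booting-stage winter
wheat. They are deliberate stand-ins: no measured per-treatment SPAD table
was available to calibrate against. A small additive fertilizer-method
effect (0--1.2 SPAD) keeps the Experiment-2 factor from being a no-op.

Measured SPAD emulates the field protocol: 5 sampling points x 10 flag
leaves x 3 meter reads, the plot value being the mean of the 50 per-leaf
read means. `leaf_sd` (default 2 SPAD) is biological leaf-to-leaf spread;
`meter_sd` (default 0.5) is per-read instrument noise, bounded above by the
+/-1.0 SPAD accuracy of the SPAD-502Plus. With 50 leaves the sampling error
of the plot mean is about `2/sqrt(50) = 0.28` SPAD, which the tests verify
against the standard-error formula.

`render_scene()` turns the design into a five-band (B, G, R, RE, NIR)
reflectance raster at 1.06 cm/pixel -- the ground sampling distance (GSD) of
a 20 m flight -- plus an integer plot mask. Within a plot, 25 cm-period row
stripes are vegetation, the rest soil; stripe width scales with a
nitrogen-driven canopy cover (`0.55 + 0.40 N/(N+120)`). Vegetation
reflectance in band b is `a_b exp(-SPAD/k_b) + c_b`: red/green/blue decrease
with chlorophyll, red-edge decreases more slowly, and NIR is dominated by
its constant term and rises slightly with SPAD. The soil spectrum is
broadband-bright with higher red reflectance than the canopy, so coarse
pixels mixing soil and rows reproduce the familiar soil-exposure confound.
Per-band Gaussian pixel noise (SD 0.01) is added and values are clipped to
[0, 1].

What this generator does *not* emulate matters for interpretation: there is
no radiative transfer, no bidirectional reflectance or illumination
variation, no shadowing, no within-plot SPAD gradient, and the
SPAD-to-reflectance map is exactly invertible up to noise. Passing tests
therefore demonstrate that the pipeline recovers a recoverable signal and
that every transformation is numerically correct -- not that a particular
accuracy will be achieved on real canopies, where test-set R^2 near 0.8 is
a realistic ceiling rather than the ~0.99 the synthetic scenes allow.

## Altitude simulation

Higher flights are simulated, not re-rendered: `resample_nearest()` degrades
the 20 m scene to the GSD of the target altitude with nearest-neighbor
index mapping (output pixel centers mapped into source coordinates, ties
toward the smaller index -- a convention we freeze since the algorithm name
alone does not determine it). Nearest neighbor creates no new pixel values,
a property the tests assert per band. GSD scales linearly:
1.06 cm/pixel at 20 m gives 2.12 at 40 m and 3.18 at 60 m. The printed
ladder many practitioners quote for 80/100/120 m (4.23/5.29/6.35 cm/pixel)
is internally inconsistent with exact 1.06-based scaling (which gives
4.24/5.30/6.36); we keep 1.06 as the documented baseline and report
two-decimal roundings of the exact linear values, noting the discrepancy
rather than resolving it.

## Features

**Vegetation indices (22).** The five plot-mean band reflectances plus 17
band combinations (NDVI, GNDVI, GRVI, NDRE, NDREI, RVI, GCI, RECI, TCARI,
MCARI, SCCCI, EVI, EVI2, OSAVI, WDRVI and the TCARI/OSAVI, MCARI/OSAVI
ratios), computed from the plot-mean reflectance (mean-then-index). Three
formulas follow the source feature table verbatim even where they differ
from textbook variants: `OSAVI = (NIR-R)/(NIR-R+0.16)`,
`EVI = 2.5(NIR-R)/(1+NIR-2.4R)` (no blue term), and
`NDREI = (RE-G)/(RE+G)`. Zero denominators yield flagged non-finite values,
never a crash.

**Texture indices (40).** Eight Haralick statistics (mean, variance,
homogeneity, contrast, dissimilarity, entropy, second moment, correlation)
per band from gray-level co-occurrence matrices in a 7 x 7 moving window at
displacement (2, 2). Unstated protocol details are frozen as: 64 gray
levels by per-band min--max quantization (a common co-occurrence default),
non-symmetric pair counting, natural-log entropy, correlation defined as 1
for zero-variance windows, and only windows fully inside a plot's mask
contribute (no cross-plot contamination). The plot feature is the mean of
each statistic over those windows. The sliding-window kernel is compiled
code; a naive double-loop oracle verifies it to 1e-10 in the tests.

**Wavelet features (20).** One level of the separable 2-D discrete wavelet
transform with the bior 1.3 biorthogonal pair (6-tap analysis low-pass,
Haar-type high-pass), symmetric half-sample extension, giving LL/LH/HL/HH
sub-images per band. The analysis low-pass sums to sqrt(2), so a constant
raster of value c yields LL = 2c exactly -- a convenient analytic anchor the
tests use, along with perfect reconstruction (<= 1e-8 on random rasters)
through the synthesis pair. How a sub-image becomes one scalar per plot is
not prescribed anywhere, so we take the mean coefficient over the plot
footprint (mask nearest-neighbor-downsampled to the sub-band grid),
consistent with how the other feature families aggregate; mean absolute
coefficient is available for the detail bands via `abs_detail = TRUE`.

## Variable selection and models

`rfe_cv()` performs recursive feature elimination with a random-forest
estimator (500 trees, impurity importance): one feature is dropped per step
from a single elimination path, and every subset size is scored by 5-fold
cross-validated R^2 with folds fixed from the seed. The "appropriate"
subset size is formalized as the argmax of the curve with ties toward the
smaller size; a one-standard-error rule is available (`rule = "onese"`)
since reading an elbow off a plot admits both interpretations. Features are
z-scored with training-fold statistics before every fit -- a no-op for the
forest itself but it keeps a single preprocessing path for all estimators.

`train_model()` fits ridge regression (glmnet, alpha = 0), random forest
(ranger), radial-kernel SVR (e1071) and a single-hidden-layer
back-propagation network (nnet) with exhaustive grid search scored by
5-fold CV R^2, then refits the winner on the full training set. The grids
are package defaults, not reported values: ridge penalty 1e-3..1e3 (log
ladder); forest 100/300/500 trees x depth unlimited/5/10; SVR cost
0.1..100, kernel width 0.1/1/10 times the 1/(p var) heuristic, tube
0.01/0.1/0.5; network 8/16/32 logistic hidden units x weight decay
1e-3/1e-2/1e-1, linear output, 2000-iteration cap, seeded initialization
(the logistic-only hidden layer is what the base-R network implementation
provides). Ridge/SVR/network consume z-scored features; the forest takes
them raw. The 8:2 split rounds the test size half-up, so 72 plots give
58/14; the same split is shared across all cells of a study (per-cell
resplitting is a flag).

## Evaluation

`compute_metrics()` reports RMSE, RRMSE = RMSE/mean(y), and
RPD = SD/RMSE, with SD the sample (n-1) standard deviation of the measured
values on the evaluated partition -- the chemometric convention; the SD of
residuals is available behind a flag because the phrase "standard deviation
between predicted and measured values" is genuinely ambiguous. Two R^2
variants are kept side by side: the conventional `1 - SSE/SST` (headline)
and the explained-variance ratio `sum((yhat-ybar)^2)/sum((y-ybar)^2)`,
which some sources print as their R^2 formula. They coincide only for exact
least-squares fits, so both are preserved rather than silently merging
them.

## The two study grids

`run_altitude_study()` evaluates VIs-only prediction at 20--120 m (six
altitudes x four models); `run_variable_set_study()` evaluates the seven
variable sets (VIs, TIs, DWT and their unions; 22/40/20/62/42/60/82
candidate columns) at the 20 m baseline. RFE is re-run per cell on the
training split. Cells that fail are logged and skipped, not fatal. Every
result table carries its master seed, a hash of the scientific
configuration, and the selected feature lists; rerunning a study with the
same seed is bit-identical down to the CSV outputs, which the tests verify
byte for byte.

## Numerical choices and problem sizes

Scenes default to the full 72-plot field at 1.06 cm/pixel (about 2600 x
4000 pixels); unit tests run the same chain at 5--8 cm/pixel, where every
plot still holds thousands of pixels, and verify the full-resolution
conditions in the acceptance suite. Monte-Carlo checks use 10,000
replicates; oracle-equivalence checks use >= 100 random windows. Noise
truncation (clipping to physical ranges) is used instead of resampling
out-of-range draws -- simpler, and exactly testable. Ties are broken
deterministically everywhere (smallest index / smallest size / first grid
point) so that a single integer seed pins down every output bit.

## Known limitations

The forward model's invertibility makes synthetic accuracies optimistic;
the generator has no illumination or canopy-structure realism; the GLCM
symmetric/non-symmetric choice and the wavelet plot-aggregation rule are
frozen conventions, not recovered facts; and the selected-feature counts on
synthetic scenes have no reason to match any particular field campaign.
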