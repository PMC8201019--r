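---
title: "Estimating soil nutrients from VIS-NIR imaging spectra: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating soil nutrients from VIS-NIR imaging spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilspec)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate,
and the choices made where the design was genuinely open.

## The estimation problem

Soil organic matter (SOM) and total nitrogen (STN) absorb in the
visible/near-infrared through C–H, N–H, –COOH and –OH overtones, so
bare-soil reflectance spectra carry a usable, if weak, nutrient signal.
A survey provides a few dozen assayed samples (here, the canonical
structure is 68 samples, SOM ≈ 11–31 g/kg with mean ≈ 19.7, STN ≈
0.8–2.1 g/kg with mean ≈ 1.4) and an imaging spectrometer provides a
reflectance cube at decimetre resolution. The task is to calibrate
`content = f(spectrum)` on the samples and invert it per pixel.

Three obstacles shape the pipeline. First, field reflectance is
contaminated by multiplicative and additive scatter (illumination,
roughness, particle size) that varies per sample and per pixel. Second,
adjacent bands are nearly collinear, and with n ≈ 55 calibration samples
against p ≈ 120 bands, unregularized regression overfits badly. Third,
flexible models (networks) are sensitive to their random initialization
at this sample size.

## Preprocessing

**MSC.** For sample spectrum $R_i$ and reference $\bar R$ (the mean
spectrum of the calibration set), ordinary least squares gives slope
$a_i$ and intercept $b_i$ in $R_{ik} = b_i + a_i \bar R_k$; the corrected
spectrum is $(R_{ik} - b_i)/a_i$. The model assumes scatter is affine in
reflectance and spectrally flat — exactly the structure the generator
plants, which is why the closed-loop tests can demand recovery at 1e-10.
A fitted slope of zero (a pathological flat sample) is a hard error
naming the sample. At prediction time the *training* reference is
reused; re-deriving a reference from each new batch or cube would shift
the model's input distribution (and, pleasantly, MSC against a fixed
reference also cancels the multiplicative stripe shading of furrowed
fields).

**SNV** standardizes each spectrum by its own mean and sample standard
deviation (m − 1 denominator, as for all standard deviations in this
package except where a population RMSE is explicitly wanted). It handles
the same effects as MSC without needing a reference, but cannot separate
slope from offset.

**Derivatives.** First and second finite differences,
$(R_{k+1}-R_k)/(\lambda_{k+1}-\lambda_k)$ and
$(R_{k+2}-2R_{k+1}+R_k)/(\lambda_{k+1}-\lambda_k)^2$, shorten the grid
by one and two bands. Output wavelengths are **left-anchored** at
$\lambda_k$; the convention is arbitrary, so it is recorded here and in
the output metadata rather than silently assumed.

**Sigma filter.** Cubes are despeckled band by band with a Lee sigma
filter: each pixel is replaced by the mean of window pixels within
`sigma_mult` (default 2) local standard deviations of the center value,
local meaning the valid pixels of the window. The default 11×11 window
matches the scale at which furrow shadows appear at 0.1 m resolution
(~1 m period). Masked pixels neither contribute to nor receive averages.

**Binning and trimming.** `bin_spectra()` re-grids by cubic spline
through the native channel centers, evaluated at the centers of
contiguous fixed-width bins spanning the native range extended by half
the native spacing (so binning an already-binned grid at its own width
is the identity; 281 channels over 400–1000 nm at 4 nm give 150 bands).
`trim_bands()` keeps bands whose center lies in closed user-given
ranges. No promise is made about the retained count for any particular
range set — it depends on the grid origin, which is why ranges are
explicit arguments.

**Diagnostics.** Per-band SNR uses the amplitude convention
$20\log_{10}(\mu/\sigma)$ in dB (configurable to $10\log_{10}$), over
samples for a matrix or valid pixels for a cube; zero deviation reports
+Inf rather than erroring. Band–property correlation scans return the
full Pearson profile plus the location of max |r|; constant bands get
r = 0 with a warning.

## Wavelength selection

**CARS.** Each of `n_runs` = 50 sampling runs: (i) draw 80% of the
calibration samples (Monte-Carlo fraction, default 0.8); (ii) fit PLSR
on the currently retained bands; (iii) enforce the exponentially
decreasing retention schedule $r_i = \mu e^{-ki}$, pinned by $r_1 = 1$
(all p bands at run 1) and $r_N = 2/p$ (two bands at run N), keeping the
top $\max(2, \mathrm{round}(r_i p))$ bands by |coefficient|; (iv)
competitively resample among the survivors with probability
proportional to |coefficient| (adaptive reweighted sampling, ARS);
(v) score the run's subset by 5-fold RMSECV, minimized over the PLSR
component count (the same cross-validation chooses the count, capped at
`max_components` = 10). The argmin-RMSECV subset over all runs is
returned, earliest run on ties. The retained-count trace is
non-increasing by construction, and the RMSECV trace typically falls
while irrelevant bands are shed and rises once informative ones start
being eliminated.

The ARS step exists in two variants. `ars_sample()` defaults to a
weighted draw **without** replacement returning exactly `count` distinct
bands — the cleaner primitive, with the properties one expects
(zero-weight bands never selected; count equal to the number of positive
weights retains all). Inside `cars()` the classic bootstrap variant is
used: `count` weighted draws **with** replacement collapsed to their
distinct outcomes, the "survival of the fittest" step of the original
algorithm. Both are exposed and tested.

**SPA.** From each candidate band as a start, a chain grows by always
adding the candidate with the largest projection norm onto the
orthogonal complement of the span of the chosen columns; exactly
collinear candidates (relative norm < 1e-10) are skipped. Every prefix
(start, N) is scored by leave-one-out RMSE of a multiple linear
regression with intercept (computed by the hat-matrix identity, so it is
deterministic), and the minimal-RMSE chain wins; ties prefer fewer
variables, then the lower starting index. Candidates are column-centered
before the projections (`center = TRUE`): on raw reflectance every
column is dominated by the shared baseline level, the first projection
step removes little else, and the chain order carries almost no
information about variance structure — centering makes the projection
geometry reflect what the collinearity argument is actually about. The
evaluation regression has an intercept either way, so scoring is
unaffected.

**CARS-SPA.** SPA runs on the CARS winner as candidate set ("secondary
screening"), with `n_max` defaulting to min(|CARS subset|, n − 3): the
LOO-RMSE criterion, not an arbitrary cap, decides how many bands
survive. Returned indices always refer to the original band grid.

## Regression

**PLSR** is NIPALS PLS1 with mean centering only (no unit-variance
scaling — bands share units, and variance scaling would inflate noise
bands), components capped at min(n − 1, p), stopping early if the
residual covariance collapses. At full rank it reproduces OLS, which the
tests exploit as an oracle. The cross-validated component choice takes
the argmin of the RMSECV curve, smaller count on ties.

**ELM.** Inputs are rescaled feature-wise to [−1, 1] using training
ranges (stored in the model; constant features map to 0). Input weights
W (L×p) and biases b (length L) are drawn uniformly from [−1, 1];
H = g(XW′ + b) with sigmoid (default) or tanh; β = H⁺y via SVD with the
standard `max(dim)·eps·max(d)` rank tolerance, giving the minimum-norm
least-squares solution. L defaults to 20 — the premise of optimizing the
input weights is precisely that a modest hidden layer then suffices.

**PSO-ELM.** Each particle encodes a full (W, b), dimension L·(p + 1),
positions in [−1, 1]. Fitness: solve β on the training portion with the
particle's (W, b), evaluate MSE on a validation set. Velocity update
$v \leftarrow wv + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)$ with
w decreasing linearly 0.8 → 0.4, c₁ = 2.4, c₂ = 1.6, swarm 100, 100
iterations; velocities are clamped to half the position range per
dimension, positions clipped to bounds, particles start uniform with
zero velocity, and the search stops early after 15 iterations without
global-best improvement beyond 1e-10. The final model re-solves β on the
complete training set with the best (W, b).

The choice of validation set deserves care: a protocol that feeds the
*test* samples' MSE to the swarm lets the search see held-out data, and
with 13 test samples the optimized network can fit them rather than the
signal. `pso_elm_fit()` therefore defaults to carving a seeded internal
validation split (20% of training) for the fitness; passing `X_val`,
`y_val` explicitly reproduces the external-validation protocol when a
comparison requires it (the CLI exposes this as `--paper-mode`). Both
paths are deterministic given the seed.

## Evaluation

`prediction_metrics()` reports R² = 1 − SS_res/SS_tot, RMSE (1/n
denominator), MAPE = 100·mean(|y − ŷ|/|y|) with zero observations
excluded under a warning, and RPD = SD(y_obs, n − 1)/RMSE (+Inf for a
perfect fit). RPD classes: > 2 accurate, (1.4, 2] moderate, ≤ 1.4 poor —
the conventional statement of the boundaries is open-ended, so boundary
values are assigned downward and documented.

`stratified_split()` ranks by target, cuts into 5 equal-frequency strata
(default), and draws per-stratum test quotas allotted proportionally by
largest remainders to a total of floor(test_fraction·n) — the floor, not
rounding, is what makes 68 samples at 20% give the conventional 55/13
split. The split is an exact partition and is seeded.

## The synthetic-data generator

The generator's defaults encode the survey structure the pipeline
assumes: n = 68 samples; 4-nm band centers 403–899 nm with the 760–782
nm water-vapour window excised (120 bands — no uniform 4-nm grid over
those ranges yields any other round count, so the package standardizes
on this grid); SOM ~ truncated normal(19.72, CV 24%) on [11.4, 30.6]
g/kg and STN ~ truncated normal(1.38, CV 22%) on [0.84, 2.08] g/kg,
sampled by rejection; per-sample scatter slope U[0.9, 1.1] and offset
U[−0.02, 0.02]; white noise SD 0.01 reflectance units.

Spectra are a smooth rising soil baseline minus Gaussian absorption
features whose depth is coefficient × content. SOM features sit in the
organic-matter-sensitive visible range 550–770 nm; STN features cluster
near 510 nm, the nitrogen-sensitive region that falls inside this
sensor's range. Gaussians are the simplest shape that reproduces smooth
single-peaked correlation profiles between bands and content. Feature
coefficients were set so absorption depths are a few hundredths of
reflectance — visible against the baseline but subordinate to scatter,
which is what makes MSC matter.

`simulate_cube()` drives per-pixel spectra from a smooth Gaussian-bump
nutrient field rescaled into the configured content range, multiplies in
a sinusoidal stripe shading of configurable period (default 1 m at 0.1 m
pixels, emulating furrow shadowing; its autocorrelation peaks at
period/pixel lag), and adds white noise. Ground truth — contents,
planted band indices, scatter pairs, shading — is returned for
closed-loop testing.

What the generator does *not* emulate: nonlinear content–depth
relations, wavelength-dependent (colored) scatter, inter-feature
correlation beyond the shared content driver, spatially correlated
noise, adjacency effects between pixels, and real soil mineralogy.
Passing closed-loop tests therefore demonstrates internal consistency
of the pipeline under its own assumptions, not field accuracy; the
headline accuracies achievable on real surveys cannot be established
from synthetic data.

A structural consequence worth noting: because every planted feature is
driven by the same content variable, feature bands are mutually
correlated through it, and a collinearity-minimizing selector is
entitled to drop some of them once one is in. The plant-and-recover
test therefore uses five equal-strength features at the noise level
where planted-band correlations sit near |r| = 0.5, and counts a
feature as recovered when a selected band lies within one 4-nm grid
step of its center (feature centers need not sit on the grid).

## Numerical choices and degenerate inputs

- Tie-breaks are deterministic everywhere: earliest run (CARS), fewer
  variables then lowest start (SPA), smaller count (PLSR components),
  lowest index (`which.min`/`which.max` conventions).
- Pseudoinverse rank tolerance: `max(dim)·eps·max(singular values)`.
- MSC slope |a| < 1e-12, SNV zero-variance rows, constant references,
  constant y in a CV fold, non-finite ELM activations: hard errors with
  the offending sample named where applicable.
- Zero SD in SNR → +Inf sentinel; constant band in correlation scans →
  r = 0 with a warning (an error would abort a whole-cube scan for one
  dead band).
- The sigma filter keeps a pixel's value when the local deviation is
  undefined (fewer than 2 valid window pixels).
- All stochastic functions take explicit seeds and restore the caller's
  RNG state, so library calls never perturb a user's stream.

## Problem sizes in the tests

The test suite exercises the full pipeline at survey scale (68 × 120
spectra, 25–30 pixel cubes, 50-run CARS, PSO swarms of 30–100), which
keeps the whole suite within a couple of minutes while leaving every
algorithmic path identical to production use; component-level oracle
checks (OLS, pseudoinverse, exhaustive SPA, brute-force sigma filter)
run at deliberately tiny sizes where the oracles are exact.

## Known limitations

- CARS's RMSECV landscape is noisy at n ≈ 55; the argmin subset can vary
  meaningfully across seeds (the band *regions* are stable, the exact
  sets are not). This mirrors the method, not a defect of the
  implementation.
- PSO-ELM with an internal validation split optimizes an 11-sample MSE
  at survey scale; gains over a well-seeded plain ELM are modest and
  occasionally negative on held-out data. The external-validation
  protocol shows larger gains but lets the search see the comparison
  set — see the discussion above.
- ENVI support covers BSQ/BIL interleaves and data types 4/5 (float,
  double), which is sufficient for reflectance products; BIP and integer
  DN rasters are out of scope.
- Grade boundaries follow the Chinese second national soil survey
  six-grade convention as a shipped default only; the grading standard
  applicable to a given survey should be supplied explicitly.
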