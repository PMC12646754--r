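---
title: "Modelling post-fire recovery of canopy 3D structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-fire recovery of canopy 3D structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firecanopy)
```

## The problem

Semi-arid woodlands dominated by obligate-seeder eucalypts are reset to age
zero by stand-replacing wildfire: the canopy trees are killed, regeneration
comes from canopy-stored seed, and the stand then develops over centuries.
Because no one can watch a 450-year recovery directly, the standard approach
is a chronosequence — a space-for-time substitution in which plots of known
time-since-fire, surveyed once with airborne laser scanning (ALS), stand in
for a single stand observed through time. `firecanopy` implements the full
analysis for such a design: plot-level structural metrics from 1 m canopy
height models (CHMs), additive smooth recovery trajectories over stand age
with rainfall and plot-size effects, derivative-based rates of change, and
the inverse problem of predicting stand age from canopy structure, validated
by stratified repeated hold-out. A two-tier synthetic generator makes every
stage testable without field data.

## Canopy structural metrics

Four metrics summarize a CHM; all are computed by `chm_metrics()` and the
individual `chm_*()` kernels.

* **H_max** — the 98th percentile of all valid pixel heights (ground zeros
  included), by the linear-interpolation quantile convention
  (`stats::quantile()` type 7). An upper percentile rather than the literal
  maximum keeps the metric insensitive to single snag spikes; `q = 1`
  recovers the exact maximum.
* **Cover** — the percentage of valid pixels *strictly* above a height
  threshold, 5 m by default. The threshold is high enough that standing dead
  stems and young regrowth do not count as canopy.
* **H_cv** — the coefficient of variation (sample sd over mean, with the
  n−1 denominator) of the pixels above the cover threshold. Computing the
  CV over canopy pixels only is a design decision: including the ground
  zeros of an open woodland makes the CV explode as cover shrinks, whereas
  the canopy-only CV stays in a bounded, interpretable range. With fewer
  than two canopy pixels the metric is undefined; the kernel signals a
  classed warning and returns `NA` rather than erroring, so degenerate
  (freshly burned) rasters still produce a metrics row.
* **Rumple_norm** — canopy rugosity: the triangulated 3D surface area of
  the height field over its ground-projected area, divided by H_max. Each
  cell of the pixel-centre grid is split into two 3D triangles along a fixed
  lower-left to upper-right diagonal (alternating diagonals are not
  implemented; the fixed choice makes the surface area reproducible to the
  last bit and is what the brute-force oracle in the test suite checks
  against). A flat canopy at height *h* gives exactly 1/*h*; an inclined
  plane of slope *s* gives √(1+*s*²)/H_max.

Mean height is also reported but deliberately excluded from the models: it
is nearly collinear with cover.

## Forward models: recovery trajectories

Each metric *Y* is modelled as

*Y* = *f*₁(stand age) + *f*₂(rainfall) + *f*₃(plot area) + ε,

a generalized additive model fitted by `fit_trajectory()` through `mgcv`.
Smooths are penalized cubic B-splines (P-splines, second-difference
penalty), basis dimension 10 per term, with smoothing parameters chosen by
REML (GCV is available via `method = "GCV.Cp"`). Tree density is fitted on
the log scale — its distribution is strongly right-skewed — and predictions
are back-transformed with the plain exponential, without a smearing
correction; at the noise levels of interest the retransformation bias is
well below the reporting precision. No age × rainfall interaction is
included: in a real chronosequence the two covariates are partially
confounded and an interaction cannot be estimated robustly, so the additive
form is a deliberate restriction, not an oversight.

Three deliberate numerical choices downstream of the fit:

* `predict_curve()` evaluates the fitted trajectory on an age grid with
  rainfall and plot area frozen at reference values (290 mm/yr and 4.4 ha by
  default). Evaluation outside the fitted age range errors unless
  explicitly allowed — penalized splines extrapolate linearly at best.
* `rate_of_change()` differentiates the curve by central finite differences
  (one-sided at the ends) and reports per-decade units; it refuses grids
  coarser than 5 yr.
* `find_extremum()` locates a peak or trough on the grid and refines it
  with a quadratic through the three neighbouring points, which is exact
  for locally parabolic curves; the mean decadal rates before and after the
  extremum are the value differences over the decades elapsed. Boundary
  extrema are flagged, not refined. Mean rates over a stated interval (not
  maximal pointwise derivatives) are the package's reading of "rate of
  rise/decline" summaries, since such rates are conventionally quoted
  alongside interval statements.

`adjusted_r2()` uses 1 − (1 − R²)(n − 1)/(n − edf − 1), with edf the summed
effective degrees of freedom of the smooths. `rainfall_contrast()` reports
the fitted difference between a wet (302 mm/yr) and dry (260 mm/yr)
reference — the 95th and 5th percentiles of a 250–330 mm/yr gradient — age
by age and at the curve's peak.

## Inverse models: predicting stand age

`fit_age_model()` flips the regression: stand age becomes the response,
and the predictors are a subset of the four structural metrics plus (always)
rainfall and plot area. `model_suite()` enumerates the standard 11-model
comparison: 4 single-metric models, 6 two-metric models, and the full
four-metric model. Predicted ages are clamped to the training age range.

`repeated_validation()` measures predictive skill by stratified repeated
hold-out: the observed age range is cut into 11 equal-length classes, a
ceiling(10%) share of each class (at least one plot from any class with two
or more; singletons stay in training) is held out, the model is fitted on
the rest, and RMSE and R² are computed on the held-out plots; the routine
repeats (500 times at production scale) with repetition *i* seeded
`seed + i − 1`, so longer runs extend shorter ones. Three conventions are
worth making explicit because the field is not consistent about them:

* Age classes span the *observed* range. A fixed class width of 35 yr and
  a fixed class count of 11 cannot both hold for an arbitrary age range;
  the class count takes precedence and the width follows.
* Validation R² is 1 − SSE/SST about the validation-set mean — not a
  squared correlation — and may legitimately be negative for a bad model;
  it is reported as computed.
* Per-age-class bias (`bias_by_age_class()`) is the pooled mean/median/IQR
  of predicted − observed age per class, using the same class breaks as the
  split.

`semivariogram()` provides the residual spatial-autocorrelation check:
binned semivariance γ(h) over plot-pair separations, flat at the residual
variance under independence.

## The synthetic chronosequence generator

The generator is calibrated, first-class code, not a test fixture. Its
defaults describe the study conditions the package is built around: 250
plots, ages 1–450 yr, rainfall 250–330 mm/yr, plot areas lognormal with
mean 4.4 and sd 2.0 ha, coordinates on a 600 × 600 km region. Ages and
rainfall are independent by default; `age_rainfall_correlation = -0.57`
reproduces the confounding typical of real fire mosaics (wetter country
burns differently), via a Gaussian copula.

**Tier A** (`simulate_plot_table()`) draws plot-level metrics from
parametric truth curves plus Gaussian noise. The curve *families* are the
package's own choice — the field knowledge being encoded is a set of anchor
features, and each family's free shape parameter is solved at construction
(`trajectory_truth()`) so the anchors hold exactly:

| metric | family | anchors enforced |
|---|---|---|
| cover | gamma-type hump | 48% at 120 yr; 20% at 450 yr |
| H_max | monomolecular rise | 15.5 m asymptote, 65 yr e-folding |
| tree density | exponential decay | ~6000/ha at age 0 → 20/ha floor |
| basal area | lognormal hump | 15 m²/ha at 160 yr; 10 m²/ha at 420 yr |
| H_cv | decay + power rise | minimum at 75 yr (young decay time solved) |
| rumple | lognormal hump | peak near 60 yr, long decline |

Solving anchors by root-finding (closed form where possible, `uniroot()`
for the H_cv decay time) means tests can assert printed features without
depending on the functional form. Unsolvable anchor combinations — an end
value above a peak — raise classed errors.

Rainfall enters linearly, scaled so the 260→302 mm/yr contrast equals
+1.2 m (H_max), +7 pp (cover), −10% relative (H_cv) and +5% relative
(rumple); field metrics get no rainfall effect by default. Plot size enters
as a coefficient on ln(area/4.4 ha), nonzero for the three scale-dependent
metrics (H_max, H_cv, rumple). Observation noise defaults (sd 1.2 m for
H_max, 7 pp cover, 0.07 H_cv, 0.04 rumple, 2.5 m²/ha basal area, 0.15
log₁₀-decades for density) are sized so that 250-plot fits show realistic
scatter yet recover the anchors; density noise acts on the log scale to
keep the distribution skewed and positive. Out-of-range noise draws are
clamped to the metric's valid range (cover to [0, 100], the rest to ≥ 0) —
a truncation by projection, chosen over rejection sampling because it
cannot loop and the induced boundary mass is negligible at default noise.

**Tier B** (`simulate_stand_scene()` + `rasterize_scene()`) builds explicit
tree lists and rasterizes them, testing the metric kernels against stands
with real geometry. Live canopy trees follow a Poisson process whose
intensity comes from the Boolean-model identity λ = −ln(1 − cover)/E[crown
area] (`boolean_density_for_cover()`), heights are normal about the truth
top height (truncated above the cover threshold), and crowns are spherical
caps with radius 0.18 × height. Snags — standing dead trees, ubiquitous
after fire in these systems — are thin spikes (≤ 0.5 m crown radius) with
heights from the mature-stand distribution, decaying with a 20-yr
half-life from 200/ha; they are the mechanism that gives young stands their
high H_cv. Rasterization max-composites crown surfaces over pixel centres.

One internal consistency limit is worth knowing: at very young ages the
default truth curves are mutually incompatible in explicit geometry — a
cover of ~18% above 5 m cannot coexist with a ~2 m top height, because any
pixel above 5 m drags the 98th height percentile up. Tier B resolves this
in favour of geometry: stands whose top height is below the cover
threshold get a sub-5 m sapling cohort (placed from the density curve)
instead of a Boolean canopy, so very young scenes have essentially zero
cover. Tier consistency between the two tiers is therefore asserted for
cover and H_max at ages 75–450 and for H_max alone at age 10.

What Tier A/B do *not* emulate: species composition, understory, canopy
gap-size structure, sensor and gridding artefacts (the CHMs are consumed as
finished products), spatially structured residuals, and any real-world age
or rainfall distribution beyond their ranges (uniform sampling is an
assumption). Passing tests show the *pipeline* recovers what the generator
encodes — they say nothing about ALS processing upstream, and real-data
explained-variance levels are not reproducible from synthetic scatter.

## Accuracy floors and known limitations

* With the default basis dimension (k = 10), a noiseless hump-shaped
  trajectory is reproduced to within about 1 percentage point sup-norm;
  k = 20 brings this below 0.25 pp. The defaults favour honest smoothing at
  field noise over noiseless-curve accuracy; raise `k` for convergence
  studies (the noiseless tests in the suite do).
* The age of a *shallow* extremum is recovered with noticeable bias: the
  H_cv valley is nearly flat for decades, and at default noise its fitted
  minimum age lands upward of the true 75 yr (typically in the 80–95 yr
  range across seeds, as the acceptance script's recomputation shows),
  while well inside the ±20 yr band that feature is asserted at. Sharp
  extrema (the cover peak) are recovered without material bias.
* Back-transformed density predictions use the naive exponential; at the
  default log-scale noise the multiplicative bias is ~1.06 and is visible
  only against the young-stand anchor, where the comparison is one-sided
  anyway.
* Problem sizes used throughout the tests and the acceptance script — 250
  plots, 10 generator seeds, 50 hold-out repetitions, 1-ha Tier B scenes —
  are the package's reporting defaults; production runs at 500 repetitions
  behave identically because the repetition seed stream is an extension,
  not a reshuffle.

## Reproducibility model

Every sampling function takes an explicit seed and restores the caller's
RNG state, so results are reproducible without global side effects. The
pipeline (`run_pipeline()`) derives a named seed per stage (generator,
validation) from one master seed, so a stage can be re-run in isolation and
reruns of the same configuration are byte-identical.
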