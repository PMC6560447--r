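---
title: "Mixture-design modelling and optimization of gluten-free bread formulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-design modelling and optimization of gluten-free bread formulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breadmix)
```

## The problem

Gluten-free batters lack the viscoelastic network that traps fermentation
gas, so formulators add hydrocolloids — here xanthan gum (XG), guar gum (GG)
and hydroxypropyl methyl cellulose (HPMC) — to recover loaf volume, crumb
softness and an open crumb grain. Because the three gums are dosed as a
*blend* with a fixed total (4% of flour weight), their effects cannot be
studied one factor at a time: the natural experimental object is a
**constrained mixture design**, and the natural model is a **Scheffé
polynomial** in the component doses.

`breadmix` implements that workflow end to end: construction of the bounded
mixture region and its D-optimal design; Scheffé two-factor-interaction (2FI)
fitting with the mixture ANOVA, lack-of-fit, PRESS and adequate-precision
diagnostics; per-formulation comparison by one-way ANOVA with Tukey HSD
compact letters; Derringer desirability optimization across several bread
quality responses; and crumb-grain image analysis (k-means segmentation into
cells and matrix, with mean cell area, cell density and void fraction). The
published design, response summaries, fitted equations and reported optimum
of a reference XG/GG/HPMC study are shipped as plain-text package data
(`reference_study()`), so every stage can be exercised against a printed
record.

## The mixture region and its design

The region is the polytope $\{\,l_i \le x_i \le u_i,\ \sum_i x_i = T\,\}$
with $T = 4$% flour weight, XG and GG in $[0.04, 0.60]$ and HPMC in
$[2.80, 3.60]$. Because of the bounds the feasible set is not the full
simplex but a pentagon embedded in it. Its corner points (**extreme
vertices**) are found by fixing all but one component at a bound and solving
the last from the total; two vertices span an edge when they share an active
bound. The classical candidate set for a constrained mixture design is the
vertices, the edge midpoints and the overall centroid:

```{r candidates}
reg <- hydrocolloid_region()
candidate_points(reg)
```

These eleven points are exactly the eleven formulations of the reference
study (the centroid (0.328, 0.328, 3.344) prints as (0.33, 0.33, 3.34) at
the study's two decimals). `d_optimal()` selects `n_runs` of them by
single-point Fedorov exchange, maximizing $\det(X^\top X)$ of the model
matrix from 20 seeded random starts. Design choices worth stating:

* **Distinct runs.** For `n_runs` up to the candidate count the design is a
  subset of distinct candidates; replicated rows are only allowed when
  `n_runs` exceeds the candidate count. Replication of a run is a
  power/pure-error decision, not a geometry decision, and a replicated
  vertex would otherwise displace the centroid on a raw determinant
  criterion.
* **Determinism.** Exchange is seeded and ties are broken first-found, so a
  seed fully determines the design. With the 11-candidate set and
  `n_runs = 11` the whole candidate set is returned; at smaller run counts
  the exchange attains the exhaustive-subset optimum on every case in the
  test suite.
* **Coding.** Coded fractions are simply dose / total (so they sum to 1);
  `design_table(..., digits = 2)` reproduces the printed table convention.
  All internal arithmetic keeps full precision.

## The Scheffé 2FI model and its diagnostics

Each quality response $Y$ is modelled without intercept as

$$Y = \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j + \varepsilon,$$

the two-factor-interaction Scheffé form; under $\sum_i x_i = T$ the linear
blending part plays the role of the intercept. `scheffe_fit()` accepts
either replicate-level observations or published per-formulation summaries
(mean, SD, n); summaries are fit by weighted least squares with the
replicate counts as weights, which reproduces replicate-level coefficients
exactly under balanced replication. When counts are unpublished, equal
weights are used and a message emitted.

The ANOVA follows the no-intercept mixture convention: the total SS is
corrected for the grand mean; the whole-model F compares the fitted model
against the grand mean; a single "linear mixture" F tests linear blending
beyond the grand mean; each interaction gets a partial (Type III) F; and
with replicate data the residual splits into lack-of-fit across the distinct
design points and pure error pooled within formulations. `fit_quality()`
reports $R^2$, adjusted and predicted $R^2$, PRESS (by the hat-matrix
identity $e_i/(1-h_{ii})$, verified in the tests against explicit
leave-one-out refits), CV, and adequate precision defined as
$(\max \hat y - \min \hat y)/\sqrt{p\,\mathrm{MSE}/n}$ — the definition used
by the mixture-design software family this workflow mirrors, since the
statistic's name alone does not pin down a formula.

Model reduction follows the published procedure: `backward_eliminate()`
refits after removing, one per pass, the least significant interaction with
$p > \alpha$ (default 0.05); linear blending terms are never removed.
`screen_outliers()` applies the published $|t| > 4$ rule on externally
studentized residuals, iteratively with a cap of three passes (the rule is
published, the iteration policy is ours), and aborts rather than empty a
formulation.

```{r svo}
ref <- reference_study()
fit <- scheffe_fit(ref$design, ref$responses$SVO,
                   terms = c("xanthan", "guar", "hpmc",
                             "xanthan:guar", "guar:hpmc"))
coef(fit)
predict(fit, c(0.24, 0.60, 3.16))  # specific volume at the reported optimum
```

A caution that the package makes explicit rather than hides: with only the
11 printed means the coefficient vector is ill-conditioned (the guar column
is nearly collinear with guar×HPMC on this small region), so means-level
refits reproduce the printed equations' *predictions* to a few thousandths
while individual coefficients can wander by ~0.1. Reproducing printed
F-statistics, $R^2$ or PRESS exactly would require the unpublished
replicate-level raw data; the tests therefore check those diagnostics
against internal oracles on simulated data, and check against the published
record only what the published record determines: predictions, dropped-term
patterns, and AdPrec > 4.

## Formulation comparison

`tukey_from_summary()` performs the one-way ANOVA/Tukey HSD comparison
directly from means, SDs and replicate counts, using the Tukey–Kramer form
for unequal counts, and encodes the result as a compact letter display via
the insert-and-absorb algorithm (two formulations share a letter exactly
when their adjusted p is at least α). On the stickiness response, where the
study states n = 10, the letters reproduce the printed superscripts exactly.

## Desirability optimization

Each goal maps a predicted response onto $[0,1]$ by a one-sided ramp between
limits $L < U$ (rising for maximization, falling for minimization, exponent
= weight), and the overall desirability is the geometric mean
$D = (\prod_n d_n)^{1/n}$ — zero whenever any individual desirability is
zero. The optimizer works on the two free coordinates (the third is
$T$ minus their sum, keeping the equality exact), screening a dense dose
grid (default step 0.01%) and polishing with Nelder–Mead from the grid
optimum and seeded random starts; infeasible proposals are rejected by
penalty.

The ramp limits are a real modelling choice, not a default to hide: the
reference study optimized specific volume (maximize) against crust
lightness, crumb hardness and cell density (minimize) without stating its
limits. With limits at the extremes of the formulation *means*, the
recomputed maximum desirability is ≈ 0.61; with limits widened to
plausible replicate-level extremes (mean ± SD·√((n−1)/n), the widest
deviation consistent with a sample of size n having that mean and SD), it is
≈ 0.57 at essentially the same composition, close to the reported 0.54.
`ramp_limits()` implements both conventions and replicate-level ranges, and
the optimizer reports the limits used.

```{r optimum}
nm <- c("SVO", "crust_L", "HARbr", "CDE")
dirs <- c("maximize", "minimize", "minimize", "minimize")
gs <- lapply(seq_along(nm), function(i) {
  l <- ramp_limits(ref$responses[[nm[i]]])
  goal(nm[i], dirs[i], l[1], l[2])
})
opt <- optimize_desirability(ref$models[nm], gs, reg, seed = 1)
opt$composition
opt$D
```

`surface_grid()` produces triangular-lattice prediction grids over the coded
simplex (clipped to the region) for ternary contour/3-D rendering; plotting
itself is left to the caller.

## Crumb-grain image analysis

A scanned slice is center-cropped to a 3.9 × 3.9 cm field at 138 px/cm,
segmented by k-means on pixel intensity (k = 2, k-means++ seeding, darker
cluster = cells since pores image darker; polarity is configurable), and
labeled with 8-connectivity; components under 4 px are discarded (the
connectivity and minimum size are unpublished in the reference procedure —
both are explicit arguments). Features are MCA (mean component area, mm²),
CDE (components per mm² of field) and VFR (cell-pixel fraction), which
satisfy VFR = CDE × MCA identically.

`synth_crumb_image()` generates the validation imagery: dark quasi-circular
cells on a bright background with Gaussian pixel noise, returning the exact
geometric ground truth. It emulates the *geometry* the features measure —
cell count, size spread, packing — not the optics of real crumb (uneven
illumination, cell-wall texture, partial-depth pores), so passing tests
certify the segmentation-to-feature pipeline, not scanner robustness.

## Synthetic replicates and what the tests mean

`simulate_responses()` draws $y_{ij} = \hat y_i + N(0, \sigma)$ around any
Scheffé model — iid Gaussian within formulation, the structure the ANOVA
assumes and the only structure the published means/SDs support. The test
suite uses it for parameter recovery (CI coverage over 500 seeds),
elimination behaviour under a true zero interaction, planted-outlier
detection, and an end-to-end simulate → fit → eliminate → optimize recovery
of the truth-model optimum (within ±0.06% dose in ≥ 90% of seeds at the
published noise scale). Problem sizes in the suite (e.g. 3–24 replicates per
formulation, 100–500 seeds, 2–3.9 cm synthetic fields) were chosen as the
smallest sizes at which the checked properties are stable.

## Known limitations

* Exact reproduction of the published F-statistics, $R^2$, PRESS and of
  every Tukey superscript is impossible without the raw replicates; only
  the stickiness letters (whose n is published) are reproduced verbatim.
* Vertex enumeration is closed-form for three components; more components
  fall back to the same bound-fixing enumeration but are not validated
  against a published design.
* Only one-sided desirability ramps are provided (the reference workflow
  used none of the two-sided "target" shapes).
* The segmentation is plain intensity k-means; no morphological
  post-processing is applied.
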