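# breadmix

Constrained mixture-design analysis for gluten-free breadmaking. The package
targets the standard formulation problem in gluten-free (GF) baking: three
hydrocolloids — xanthan gum (XG), guar gum (GG) and hydroxypropyl methyl
cellulose (HPMC) — are blended at a fixed total of 4% flour weight, and
batter/bread quality responses (batter stickiness and firmness, loaf
specific volume, baking loss, water activity, crust/crumb lightness, TPA
texture, and crumb-grain image features) are modelled and jointly optimized
over the blend.

It is written for food scientists and applied statisticians who work with
mixture experiments and want the full workflow in one place:

* **Region & design** — extreme vertices, edge centroids and overall
  centroid of the bounded region `{l ≤ x ≤ u, Σx = 4%}`; D-optimal run
  selection by seeded Fedorov point exchange (`hydrocolloid_region()`,
  `candidate_points()`, `d_optimal()`).
* **Scheffé 2FI modelling** — the no-intercept mixture polynomial
  `Y = Σ βᵢxᵢ + Σ βᵢⱼxᵢxⱼ`, fit to replicate data (OLS) or to published
  means/SD/n summaries (WLS); mixture ANOVA with linear-mixture and partial
  interaction F-tests, lack-of-fit vs pure error; R², adjusted/predicted R²,
  PRESS by the hat-matrix identity, CV and adequate precision; backward
  elimination of non-significant interactions; iterative screening of
  externally studentized residuals beyond |t| = 4
  (`scheffe_fit()`, `anova()`, `fit_quality()`, `backward_eliminate()`,
  `screen_outliers()`).
* **Group comparison** — one-way ANOVA + Tukey HSD directly from summary
  statistics (Tukey–Kramer for unequal n) with compact letter displays
  (`tukey_from_summary()`).
* **Desirability optimization** — Derringer one-sided ramps and
  geometric-mean overall desirability `D = (Π dₙ)^(1/n)`, maximized over the
  mixture region by grid screen plus Nelder–Mead polish
  (`goal()`, `ramp_limits()`, `optimize_desirability()`, `surface_grid()`).
* **Crumb-grain imaging** — center crop, k-means binary segmentation
  (darker phase = pores), 8-connected labeling, and the features MCA (mean
  cell area, mm²), CDE (cell density, cells/mm²) and VFR (void fraction)
  (`crumb_image()`, `crop_center()`, `kmeans_segment()`,
  `grain_features()`, `synth_crumb_image()`).
* **Reference data & simulation** — the published 11-run design, response
  summaries, fitted equations and reported optimum of a XG/GG/HPMC study
  ship as plain-text data (`reference_study()`); `simulate_responses()`
  generates replicate-level Gaussian data around any model for validation.

See `vignette("hydrocolloid-mixtures")` for the methods account.

## Worked example

```r
library(breadmix)

reg  <- hydrocolloid_region()          # XG, GG in [0.04, 0.60], HPMC in [2.80, 3.60], total 4
cand <- candidate_points(reg)          # 5 vertices + 5 edge midpoints + centroid
des  <- d_optimal(cand, reg, n_runs = 11, model = "2fi", seed = 1)
design_table(des, digits = 2)[, 1:5]
#>    formulation_id             role xanthan guar hpmc
#> 1               1           vertex    0.04 0.36 3.60
#> 2               2           vertex    0.04 0.60 3.36
#> ...
#> 11             11 overall-centroid    0.33 0.33 3.34
```

The 11 runs are the realized design of the reference study. Fitting the
specific-volume response to the published formulation means with the
study's retained term set:

```r
ref <- reference_study()
fit <- scheffe_fit(ref$design, ref$responses$SVO,
                   terms = c("xanthan", "guar", "hpmc",
                             "xanthan:guar", "guar:hpmc"))
round(coef(fit), 3)
#>      xanthan         guar         hpmc xanthan:guar    guar:hpmc
#>        1.383       -1.127        0.588        0.464        0.522
round(predict(fit, c(0.24, 0.60, 3.16)), 2)
#> [1] 2.57
```

The refit predicts 2.57 mL/g at the blend (0.24% XG, 0.60% GG, 3.16% HPMC) —
the study's reported optimum value (its printed equation gives the same
2.57). Joint optimization of four quality goals with reconstructed ramp
limits:

```r
nm   <- c("SVO", "crust_L", "HARbr", "CDE")
dirs <- c("maximize", "minimize", "minimize", "minimize")
gs   <- lapply(seq_along(nm), function(i) {
  l <- ramp_limits(ref$responses[[nm[i]]])
  goal(nm[i], dirs[i], l[1], l[2])
})
opt <- optimize_desirability(ref$models[nm], gs, reg, seed = 1)
round(opt$composition, 3)   # xanthan 0.215, guar 0.600, hpmc 3.185
round(opt$D, 3)             # 0.572
round(opt$predictions, 3)   # SVO 2.551, crust_L 66.918, HARbr 2018.746, CDE 0.136
```

i.e. within 0.025% dose of the study's reported optimum and close to its
reported desirability of 0.54 (the exact value depends on the unpublished
ramp-limit convention; see the vignette). Crumb-grain features from a
synthetic slice:

```r
syn <- synth_crumb_image(n_cells = 40, radius_px = 5, field_cm = 2.5,
                         ppcm = 138, noise_sd = 8, seed = 7)
grain_features(kmeans_segment(syn$image, seed = 1), syn$image)
#> Grain features: MCA 0.414 mm^2, CDE 0.0640 cells/mm^2, VFR 0.026 (40 cells)
```

MCA here matches the disc geometry π(5·10/138)² ≈ 0.413 mm².

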