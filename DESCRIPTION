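Package: breadmix
Title: Mixture-Design Modelling and Optimization of Gluten-Free Bread Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constrained mixture experiments on hydrocolloid blends in
    gluten-free breadmaking: extreme-vertex candidate construction and D-optimal
    design selection over a bounded three-component simplex, Scheffe
    two-factor-interaction response-surface fitting with mixture ANOVA,
    lack-of-fit, PRESS and adequate-precision diagnostics, one-way ANOVA with
    Tukey HSD compact letter displays, Derringer desirability multi-response
    optimization, and crumb-grain image analysis (k-means segmentation, mean
    cell area, cell density and void fraction). Ships the published design,
    response summaries and fitted coefficients of a xanthan/guar/HPMC study as
    reference data, plus a synthetic replicate and crumb-image generator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
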