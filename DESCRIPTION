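Package: tvide
Title: Time-Varying Intercept Models for Longitudinal Differential
    Expression in Stent Restenosis Cohorts
Version: 0.1.0
Authors@R:
    person("CardioGene", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genes whose peripheral-blood expression trajectories
    differ between patients who do and do not develop in-stent restenosis
    after bare-metal stenting.  Expression sampled at irregular times
    post-stent is modelled with a B-spline time-varying intercept; group
    differences are scored by the relative improvement in residual sum of
    squares when each group receives its own time curve, with significance
    from a subject-block residual bootstrap and Benjamini-Hochberg or
    Storey q-values.  Includes probe-level quality-control filtering,
    age/sex covariate adjustment, sex-concordance checking by nearest
    shrunken centroids or linear discriminant analysis, replication
    testing in an independent cohort, a random-probe-set sensitivity
    analysis, Fisher/EASE over-representation of annotation categories,
    and a synthetic-cohort generator emulating the CardioGene and deCODE
    longitudinal designs with per-gene ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    parallel,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
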