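Package: cortexdev
Title: Developmental Cortical Microstructure and Cell-Type Expression Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying cortical development jointly from
    in vivo microstructural MRI summaries and post-mortem gene expression.
    Provides synthetic-data generators emulating an adolescent imaging cohort
    (network-level SANDI/NODDI/DTI and morphology metrics), a small test-retest
    repeatability study, and two developmental brain expression datasets;
    network-level standardized linear models with AIC model selection and
    two-way random-effects absolute-agreement ICC; per-gene penalized-spline
    age trajectory modelling with FDR gene selection, cell-type trajectory
    summaries, peak-growth and glial expression-ratio crossover estimation,
    and Fisher-test gene-set enrichment; and a cell-composition simulation of
    the MR apparent soma radius based on higher-order moments of voxel-scale
    cell body radius distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    jsonlite,
    mgcv,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
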