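Package: preemiegut
Title: Longitudinal Analysis of Gut Microbiota Succession in Preterm Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal 16S rRNA count data from
    preterm-infant cohorts: rare-taxon filtering, dominance-phase
    classification, Bray-Curtis ordination with a postmenstrual-age
    development index, permutational multivariate ANOVA with sequential
    covariate partitioning, penalized negative-binomial spline models of
    taxon abundance with read-count offsets and per-infant intercepts,
    antibiotic-course responder classification from model residuals,
    sepsis-window abundance comparisons, and exact 2x2 cohort statistics.
    Includes a seeded synthetic-cohort simulator that reproduces the
    statistical structure the analyses assume (four-phase succession over
    postmenstrual age, Dirichlet-multinomial counts, antibiotic responder
    mixtures, sepsis events), so every stage is testable without access to
    clinical sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    splines,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mgcv,
    MASS,
    withr
Config/testthat/edition: 3
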