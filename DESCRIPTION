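Package: esmgxe
Title: Gene-Environment Interaction Analysis for Experience Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genetic sensitivity to daily-life context with
    experience sampling (ESM) data. Implements clumping-and-thresholding
    polygenic scores from genotype dosages and GWAS summary statistics,
    construction of within-day time-lagged beep pairs and momentary symptom
    indices, maximum-likelihood random-intercept linear mixed models, and a
    competitive-confirmatory classification of cross-level gene-by-environment
    interactions into differential-susceptibility, diathesis-stress and
    vantage-sensitivity patterns (weak and strong variants) using
    crossover-point reparameterizations, AIC model competition and parametric
    bootstrap confidence intervals for the crossover point. A hierarchical
    synthetic-data generator (block-LD genotypes, GWAS-like summary statistics,
    signal schedules and 7-point item responses under a configurable true
    G-by-E regime) makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
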