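Package: episignr
Title: DNA Methylation Episignature Discovery, Scoring and Regional Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering and applying DNA
    methylation episignatures from Illumina-style methylation arrays.
    Starting from a normalized beta-value matrix and a sample sheet, the
    package performs probe quality control, logit (M-value) transformation,
    age/sex-matched control selection, reference-based blood cell
    deconvolution, per-probe linear modelling with empirical-Bayes variance
    moderation, a four-stage probe-selection cascade (effect size, adjusted
    p-value, ROC AUC, correlation pruning), support-vector-machine
    pathogenicity (MVP) scoring with one-against-all multi-syndrome models,
    rule-based differentially methylated region (DMR) calling with
    Fisher-combined p-values, and comparison of DMR-associated gene
    expression against background genes. A synthetic-cohort generator with
    planted signature probes, a methylation dose effect, cell-composition
    confounding and co-located CpG clusters makes every stage testable
    without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    e1071,
    pracma
Suggests:
    testthat (>= 3.0.0),
    limma,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
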