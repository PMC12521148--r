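Package: qalytree
Title: Decision-Tree Cost-Utility and Cost-Effectiveness Analysis of
    Pediatric Asthma Inhaler Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pharmacoeconomic evaluation of inhaled corticosteroid (ICS) and
    ICS-LABA maintenance strategies for pediatric asthma. Implements a
    three-state (hospitalization, outpatient exacerbation, symptom-free)
    decision-tree cost-utility model with QALY utilities derived from a base
    utility and per-state decrements over a fixed horizon, state probabilities
    derived as visit shares, cost-effectiveness and incremental
    cost-effectiveness (ICER) tables with dominance classification,
    incremental cost-utility ratios (ICUR) against a willingness-to-pay
    threshold, net monetary benefit, probabilistic sensitivity analysis with
    Gamma cost priors and Dirichlet probability priors (cost-effectiveness
    plane, confidence ellipse, acceptability curves), and a synthetic
    patient-level cohort generator that reproduces the study's marginal
    structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
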