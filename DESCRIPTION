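Package: cvdbn
Title: Bayesian Network Analysis of Metabolic Obesity Phenotypes and
    10-Year Cardiovascular Disease Risk
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how metabolic health and body-mass-index
    categories relate to 10-year cardiovascular disease (CVD) risk in adult
    cohorts. Provides a seeded synthetic cohort generator that mirrors the
    metabolic-obesity phenotype structure of a Chinese population survey;
    phenotype derivation (Adult Treatment Panel-3 metabolic health, Chinese
    BMI categories, HOMA-IR, CKD-EPI eGFR, comorbidity flags); the
    sex-specific Framingham general-CVD 10-year risk score with eligibility
    filtering; constrained score-based discrete Bayesian network structure
    learning (tabu search with BIC scoring, whitelist/blacklist and layer
    constraints); bootstrap arc-strength model averaging with thresholded
    consensus networks; conditional probability table estimation; and exact
    and likelihood-weighted conditional probability queries with Monte Carlo
    confidence intervals, orchestrated end to end by a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
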