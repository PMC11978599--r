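Package: brainclock
Title: Plasma Proteomic Brain-Age Clocks and Brain Age Gap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds brain-enriched plasma proteomic age clocks and analyses
    the resulting brain age gap. Provides tissue-enrichment classification of
    genes from bulk expression matrices, protein-level quality control,
    gradient-boosted age prediction with shadow-feature (Boruta) selection and
    Shapley importance, locally weighted (LOESS) detrending of predicted age
    to obtain a decorrelated brain age gap z-score, extreme-ager and quartile
    classification, a covariate-tiered Cox proportional-hazards association
    battery with restricted-cubic-spline nonlinearity tests, Schoenfeld
    diagnostics, Fine-Gray competing-risks sensitivity analyses and subgroup
    interaction tests, and association of the gap with residualized brain MRI
    volume phenotypes. A synthetic cohort generator with a latent per-person
    aging rate drives end-to-end testing without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    cmprsk,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
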