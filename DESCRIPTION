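Package: txage
Title: Transcriptomic Age from Multi-Cohort Blood Expression Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-cohort analysis of age-associated blood gene
    expression: per-cohort linear association models, sample-size-weighted
    (Stouffer) meta-analysis with discovery/replication gating, Sobel tests
    for methylation-mediated age effects with matched-control enrichment,
    and a summary-statistic ridge ("BLUP from meta-analysis z-scores")
    transcriptomic age predictor with leave-one-out cross-cohort validation,
    delta age, and delta-age/phenotype association. Includes a synthetic
    multi-cohort data generator with known truth so the whole pipeline runs
    and can be scored without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
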