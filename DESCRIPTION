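Package: ComorbidEHR
Title: Replicated Case-Control Comorbidity Enrichment and Patient
    Stratification for EHR Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenome-wide comorbidity analysis of electronic health
    record (EHR) cohorts built from OMOP-style flat tables. Cases are defined
    by a concept-set closure over a condition hierarchy, and compared against
    thirty replicate propensity-matched control groups. Per-condition
    enrichment is scored with the hypergeometric test, Bonferroni-corrected
    within each replicate, and aggregated as twice the mean corrected p-value;
    a utilization-matched control arm filters associations driven by
    healthcare contact frequency. Cases are stratified by Leiden community
    detection on a nearest-neighbour graph of their PCA-reduced binary
    diagnosis matrix, clusters are characterised by enriched and exclusive
    conditions, and association and clustering results are compared across
    data sources (significant-set overlap, log-odds-ratio correlation,
    greatest-overlap cluster matching with Jaccard similarity). A synthetic
    cohort generator with planted effects, utilization confounding and latent
    patient subgroups supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    igraph,
    glmnet,
    RANN,
    uwot,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
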