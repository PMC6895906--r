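Package: neurosim
Title: Genetic, Cell-Type and Brain-Region Similarity of Nervous System Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying similarity between heritable diseases of the
    nervous system from pathogenic-mutation catalogs. Merges curated and
    ClinVar-style disease-mutation tables with inclusion-exclusion accounting,
    screens all disease pairs for excess gene (or mutation) sharing with a
    chi-square test, builds per-disease enrichment profiles over cell-type
    marker catalogs and over brain-region highly-expressed gene sets (called by
    an empirical-Bayes moderated region-versus-rest contrast), compares
    profiles with an asymmetric binary distance, and relates every similarity
    layer to phenotype-similarity scores by correlation and ranked three-group
    comparison. A synthetic-data module generates all five input kinds with
    planted ground truth so each stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
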