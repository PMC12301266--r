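Package: imdsig
Title: Metabolic Signature Discovery and Ranked Diagnosis of Inherited
    Metabolic Disorders from Untargeted Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers per-disorder metabolic signatures from untargeted
    LC-MS feature tables using sparse hierarchical clustering feature
    weights, refines the signatures iteratively as new patient samples
    arrive, and ranks candidate inherited metabolic disorders for an
    undiagnosed sample by normalized dot-product similarity against the
    signature store. Includes pooled-QC peak filtering, internal-standard
    normalization, limit-of-detection imputation, control-referenced
    Z-scoring, a repeated random sub-sampling cross-validation harness
    with rank-1/2/3 reporting, and a seeded synthetic cohort generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
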