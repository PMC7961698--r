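Package: spheroprog
Title: Expression-Program Discovery and Stem-Cell Frequency Estimation for
    Tumor Spheroid Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting intra-tumor heterogeneity in patient-derived
    colorectal cancer spheroid cultures from single-cell RNA-seq counts:
    quality-control filtering, log2 counts-per-million normalization,
    expression-level gene filtering, per-patient mean-centering, cross-patient
    non-negative matrix factorization (NNMF) to discover cell-type and
    cell-state expression programs, exclusion of patient-specific factors,
    background-binned signature scoring, and threshold-based cell-type
    assignment. Also included: signature scoring of bulk cohorts with a
    progressive six-cluster stratification and survival comparison
    (Kaplan-Meier, log-rank, nested Cox models), single-hit Poisson
    maximum-likelihood estimation of spheroid-forming and tumor-initiating
    cell frequencies from limiting-dilution assays, and a synthetic-data
    generator that emulates the multi-patient count structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    survival,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
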