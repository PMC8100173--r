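Package: scITH
Title: Copy-Number and Intratumor Heterogeneity Analysis for Single-Cell
    NSCLC Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying intratumor heterogeneity in
    multi-patient non-small cell lung cancer (NSCLC) single-cell RNA-seq
    cohorts. Provides knee-based cell calling and cell-level quality control,
    expression-inferred relative copy-number profiles (genomic window
    smoothing against a non-malignant baseline), CNA- and expression-based
    intratumor heterogeneity scores (interquartile range of pairwise Pearson
    correlations among malignant cells), marker-score cell typing with
    LUAD/LUSC patient classification, ligand-receptor interaction testing by
    cell-label permutation with specificity-rank and patient-recurrence
    filters, and cell-type / gene interaction networks. A negative-binomial
    cohort simulator with known clones, copy-number segments, marker programs
    and planted ligand-receptor signals makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
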