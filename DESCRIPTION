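Package: lipochemo
Title: Chemometric Profiling of Lipophilicity Measures and GA-PLS QSRR
    Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing computational and chromatographic
    lipophilicity scales of small drug-like molecules. Implements the
    chromatographic-hydrophobicity-index transforms to log k(IAM) and
    CHI logD, consensus logP, sum of ranking differences (SRD) with the
    comparison-of-ranks-by-random-numbers (CRRN) null distribution,
    k-fold SRD cross-validation and Wilcoxon matched-pair grouping,
    correlation/PCA/Ward cluster analysis of standardized lipophilicity
    tables, and genetic-algorithm partial-least-squares (GA-PLS)
    descriptor selection with external-validation statistics
    (Q2F1/Q2F2/Q2F3, RMSEP, CCC), y-randomization, and a leverage-based
    applicability domain. Ships a 27-compound sulfonamide lipophilicity
    dataset as plain-text fixtures plus seeded synthetic-data generators
    so the whole analysis is reproducible offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
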