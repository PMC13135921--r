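Package: pircher
Title: Indirect Allorecognition Epitope Scoring and dnDSA Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a PIRCHE-T2-style scoring engine for indirect
    allorecognition in organ transplantation: enumeration of mismatched
    donor-derived HLA 15-mer peptides, self-peptide filtering, peptide-MHC
    class II binding assessment through a pluggable predictor interface (with
    a deterministic seeded surrogate supplied), and counting of unique
    peptide-presenter tuples per locus, per class, and in total under both an
    affinity-threshold and a percentile-rank binding criterion. Also provides
    a synthetic two-center kidney-transplant cohort simulator with
    proportional-hazards time-to-dnDSA outcomes and center-specific antibody
    review policies, plus the associated risk-stratification evaluation
    battery: Wilcoxon score comparisons, ROC/AUC with DeLong confidence
    intervals and Youden thresholds, tertile and binary threshold
    stratification with threshold recalibration, Kaplan-Meier curves with
    log-rank tests, and Cox proportional hazards models with hazard ratios
    and Harrell's concordance index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    survival,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
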