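Package: mirpair
Title: Pairwise Ct-Ratio Biomarker Discovery for Circulating miRNA qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering diagnostic microRNA biomarkers from two-cohort
    RT-qPCR panel data. Raw cycle-threshold (Ct) values are normalized by forming
    all pairwise within-sample Ct differences (equivalently, 2^dCt expression
    ratios), which cancels per-sample technical offsets without reference genes.
    Every pair is evaluated as a binary classifier (logistic regression, ROC/AUC
    with DeLong or bootstrap confidence intervals, Mann-Whitney tests), pairs
    passing an AUC gate feed an exhaustive equal-weight k-pair combination
    search, and plasma/tissue profile concordance can be quantified. A seeded
    synthetic two-cohort qPCR generator with a ground-truth table supports
    end-to-end validation without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
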