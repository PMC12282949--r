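Package: cnagain
Title: Low-Amplitude Copy-Number-Gain Analysis for Cancer Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for somatic copy-number gains of low
    amplitude (whole-arm and focal single-copy gains) across cancer
    cohorts: centromere-aware genomic binning with weighted-mean segment
    copy numbers, discrete gain/loss/amplification calling at bin, arm
    and gene level, differential CRISPR-dependency and drug-response
    association testing with Storey q-values and preranked gene-set
    enrichment, elastic-net biomarker selection with replicate
    intersection, and per-bin Cox survival scoring. Includes a
    synthetic-cohort generator with a machine-readable truth ledger so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
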