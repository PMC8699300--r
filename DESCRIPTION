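Package: epialleler
Title: Single-Molecule Methylation Pattern Analysis of Targeted Bisulfite Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locus-specific, single-molecule DNA methylation analysis
    of dual-barcoded bisulfite amplicon sequencing data, aimed at cell-free DNA
    liquid-biopsy studies. Processes paired or merged amplicon reads into
    per-molecule CpG methylation pattern tables (demultiplexing with chimeric
    barcode-pair exclusion, per-read bisulfite conversion-rate filtering),
    enumerates single- and joint-position methylation-status variables,
    and screens them for group discrimination with exact Mann-Whitney tests,
    Bonferroni adjustment, separation cutoffs, balanced-weight leave-one-out
    cross-validated logistic regression, and DeLong ROC AUC confidence
    intervals. Includes a calibrated synthetic-cohort generator with known
    ground truth and a binary-variable re-screen for low-coverage per-read
    whole-genome bisulfite sequencing call tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
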