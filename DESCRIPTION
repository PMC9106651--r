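Package: cnstriage
Title: Two-Stage Whole-Genome Sequencing Triage for Fetal CNS Anomalies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a prenatal whole-genome-sequencing
    diagnostic workflow for fetal central nervous system anomalies: a low-pass
    read-depth screen for aneuploidies and large copy-number variants, a
    phenotype-driven (HPO candidate gene) tiered single-nucleotide-variant
    triage, intragenic copy-number assessment, and a case-control rare
    singleton loss-of-function variant burden analysis with a two-sided
    Wilcoxon rank-sum comparison. Ships a synthetic cohort generator with
    spike-in truth tables so every stage is testable without access to
    patient-level data, plus a curated plain-text fixture re-encoding the
    published cohort summary tables for end-to-end reporting checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
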