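Package: cfscreen
Title: Quantitative Cell-Free DNA Biomarkers and Stabilized Decision Trees
    for Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for cancer-screening studies built on
    quantitative and structural features of circulating cell-free DNA
    (cfDNA). Converts Q-PCR concentrations into nuclear and mitochondrial
    copy numbers per mL of plasma, derives the mitochondrial-to-nuclear
    ratio (MNR) and the cfDNA integrity index (DII), and applies
    sample-level quality-control filters. Provides a calibrated synthetic
    cohort simulator, age-stratified case-control resampling, per-marker
    ROC analysis with closest-to-ideal-corner optimal thresholds and
    empirical (basic) bootstrap confidence intervals, a from-scratch
    recursive-partitioning tree engine with resampled variable-importance
    screening, and an iterative decision-tree builder that stabilizes each
    node by resampled variable selection and bootstrap-median thresholds
    before descending. Includes tree evaluation on training, held-out,
    early-stage and cross-cohort sets, a stability comparison against
    conventional single-fit trees, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
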