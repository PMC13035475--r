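Package: mosaicpool
Title: Analysis of Pooled Multi-Cell-Line Single-Cell Drug-Response Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mosaic-tumor ("pooled") drug-response assays in which
    many genetically distinct cancer cell lines are mixed in one culture or
    xenograft, treated, and read out by single-cell RNA sequencing. Covers
    the full desk-side analysis path: SNP-based genotype demultiplexing and
    hashtag (HTO) sample assignment with doublet detection; apoptotic-cell
    flagging and cell-cycle phase scoring; per-line drug-sensitivity
    phenotypes from pool representation (relative survival, log-log dose
    slopes, pool-balancing seed counts, mutation-covariate lasso);
    Gini/mutual-information heterogeneity statistics with permutation nulls;
    cross-model differential expression aggregation with bootstrap
    significance and model-downsampling curves; Bliss-independence drug
    synergy on survival and on G1-arrest phenotypes plus gene-level synergy
    covariates from negative-binomial pseudobulk models; and guide-to-gene
    rho aggregation for pooled CRISPRi screens. A synthetic-data generator
    with known ground truth emulates the structure of such experiments for
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    MASS,
    glmnet,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
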