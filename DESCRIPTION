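Package: knockdownDE
Title: Beta-Poisson Differential Expression for Single-Cell siRNA
    Knockdown Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential-expression analysis of single-cell RNA-seq
    knockdown experiments in which the per-cell expression of the silenced
    target gene stratifies treated cells into dosage groups. Implements
    detection-rate quality control and counts-per-million normalization,
    a protected-covariate latent-factor correction for cell-cycle/batch
    confounding, per-gene beta-Poisson generalized linear models with
    likelihood-ratio tests under two-group and three-group (dosage)
    designs, Fisher's-method combination of per-coefficient p-values,
    Benjamini-Hochberg FDR, overlap and direction-bias summaries, and a
    truth-tracking synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: SingleCell, DifferentialExpression, RNASeq, Regression,
    BatchEffect, Software
RoxygenNote: 7.3.3
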