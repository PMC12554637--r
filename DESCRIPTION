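Package: treeDE
Title: Tree-Guided Bayesian Differential Expression for Single-Cell RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pseudo-bulk differential expression testing for single-cell
    RNA-seq that shares information across correlated cell types. Cell
    types are organised in a hierarchical tree estimated from the
    correlation of per-cell-type DE test statistics; tree-structured
    Bernoulli priors on latent DE states are combined with Gaussian
    likelihoods on normalized pseudo-bulk expression, and per-gene,
    per-cell-type posterior DE probabilities are computed by exact
    enumeration over all DE-state configurations. Includes a
    negative-binomial single-cell count simulator with tree-correlated DE
    truth and benchmarking utilities (precision-recall curves, observed
    FDR, label permutation, rediscovery rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    ape,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
biocViews: SingleCell, DifferentialExpression, Bayesian, GeneExpression,
    Transcriptomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
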