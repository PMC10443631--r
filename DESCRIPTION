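Package: MarrowDivergence
Title: Cross-Bone Single-Cell Divergence, Differential Expression and
    Ligand-Receptor Permutation Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistics for comparing bone-marrow (and meningeal/brain)
    scRNA-seq compartments across anatomical regions and injury conditions:
    an eigenvalue-weighted principal-component regression divergence score
    with a label-permutation null, a gap-split combinatorial differential
    expression test that orders regions by mean expression and splits at the
    largest gap, gene-set inflammation scores, region dendrograms on averaged
    principal components, and a balanced-sampling ligand-receptor permutation
    analysis with cross-region common/unique interaction calls. Includes
    quality-control filters, cluster-based size-factor normalization,
    per-sample highly-variable-gene selection, a negative-binomial cohort
    simulator with planted ground truth for calibration and power studies,
    and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    scran,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, DifferentialExpression,
    DimensionReduction, Normalization
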