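Package: scregulon
Title: Cross-Validated Regulon Discovery and Differential-Distribution
    Analysis for Single-Cell RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying transcription-factor programs along
    hematopoietic (B-lymphoid) differentiation in single-cell RNA-seq
    data. Implements balanced-sampling, cross-validated regulon discovery
    with signed (activating/repressive) target inference, AUC
    recovery-curve activity scoring and reproducibility filters;
    differential expression-distribution calling with an explicit
    zero-proportion (DZ) category; correlation-distance k-means
    clustering of zero-proportion profiles across cell states; quality
    control including per-cluster median-absolute-deviation outlier
    removal, normalization, highly variable gene selection and cell-cycle
    scoring; and peak-to-gene association via basal-plus-extension
    regulatory domains for validating inferred target sets against
    ChIP-seq or ATAC-seq peaks. A synthetic-data generator with planted
    regulons, dropout and donor effects provides ground truth for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    MASS,
    mclust,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    IRanges,
    GenomicRanges,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
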