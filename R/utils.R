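#' @importFrom methods is
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats cor median p.adjust rnbinom rnorm runif rbinom quantile
#'   pt sd var fisher.test wilcox.test rlnorm lm coef predict complete.cases
#' @importFrom utils read.table write.table head
NULL

# Derive a reproducible 32-bit sub-seed from a master seed and a stream index.
# Keeps every stage of a pipeline on its own stream so that inserting cells
# or genes upstream does not perturb unrelated stages.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807 + 1) %%
               2147483647)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Extract a genes x cells matrix from either a plain matrix-like object or a
# SingleCellExperiment (assay chosen by name, first assay as fallback).
get_matrix <- function(x, assay = NULL) {
  if (is(x, "SummarizedExperiment")) {
    nms <- SummarizedExperiment::assayNames(x)
    if (is.null(assay)) assay <- nms[1L]
    if (!assay %in% nms) {
      stop("assay '", assay, "' not found; available: ",
           paste(nms, collapse = ", "))
    }
    SummarizedExperiment::assay(x, assay)
  } else {
    x
  }
}

# Dense numeric copy; keeps dimnames.
as_dense <- function(m) {
  if (is(m, "Matrix")) as.matrix(m) else as.matrix(m)
}

# Column-wise Pearson correlation helper that tolerates zero-variance columns
# (returns NA there instead of warnings).
safe_cor <- function(x, y) {
  suppressWarnings(cor(x, y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
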