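#' Write a simulated (or real) dataset to disk
#'
#' Writes the standard 10x-style triplet — `matrix.mtx` (MatrixMarket
#' coordinate, 1-based), `features.tsv`, `barcodes.tsv` — plus
#' `cell_metadata.tsv` and, when truth is present, `truth.json`. The layout
#' round-trips losslessly through [read_dataset()].
#'
#' @param dataset A list with `sce` (and optionally `truth`), as returned by
#'   [simulate_counts()] / [simulate_dataset()], or a bare
#'   SingleCellExperiment.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, out_dir) {
  if (is(dataset, "SingleCellExperiment")) {
    dataset <- list(sce = dataset,
                    truth = S4Vectors::metadata(dataset)$truth)
  }
  sce <- dataset$sce
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  m <- methods::as(get_matrix(sce, "counts"), "CsparseMatrix")
  mtx <- file.path(out_dir, "matrix.mtx")
  Matrix::writeMM(m, mtx)
  writeLines(rownames(sce) %||% character(0),
             file.path(out_dir, "features.tsv"))
  writeLines(colnames(sce) %||% character(0),
             file.path(out_dir, "barcodes.tsv"))
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  meta <- cbind(barcode = rownames(meta), meta)
  write.table(meta, file.path(out_dir, "cell_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c("matrix.mtx", "features.tsv", "barcodes.tsv",
             "cell_metadata.tsv")
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    truth$mu <- NULL # latent matrices are oracle-only, not serialized
    truth$phi <- NULL
    truth$config <- unclass(truth$config)
    truth$planted_regulons <- lapply(truth$planted_regulons, unclass)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, "truth.json")
  }
  invisible(file.path(out_dir, files))
}

#' Read a dataset written by [write_dataset()] (or any 10x-style triplet)
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, and optionally `cell_metadata.tsv` / `truth.json`.
#' @return A list with `sce` and `truth` (NULL if no truth file).
#' @export
read_dataset <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feats <- readLines(file.path(dir, "features.tsv"))
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(feats, bcs)
  cd <- S4Vectors::DataFrame(row.names = bcs)
  meta_path <- file.path(dir, "cell_metadata.tsv")
  if (file.exists(meta_path)) {
    meta <- read.table(meta_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, check.names = FALSE)
    rownames(meta) <- meta$barcode
    cd <- S4Vectors::DataFrame(meta[bcs, setdiff(names(meta), "barcode"),
                                    drop = FALSE])
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd)
  truth <- NULL
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    if (!is.null(truth$planted_regulons)) {
      regs <- truth$planted_regulons
      if (is.data.frame(regs)) regs <- split(regs, seq_len(nrow(regs)))
      truth$planted_regulons <- lapply(seq_along(regs), function(i) {
        r <- as.list(regs[[i]])
        regulon(tf = r$tf[[1]], sign = r$sign[[1]],
                targets = unlist(r$targets),
                npred = if (is.null(r$npred)) NULL else unlist(r$npred),
                active_states = unlist(r$active_states))
      })
    }
    S4Vectors::metadata(sce)$truth <- truth
  }
  list(sce = sce, truth = truth)
}
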