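#' Quality-control thresholds
#'
#' Cell rules: a cell is removed when its mitochondrial UMI fraction is
#' strictly above `max_mito_frac`, or its total UMI count is
#' `max_total_umi` or more, or it expresses `max_genes_per_cell` genes or
#' more (the latter two flag likely doublets). Gene rule: genes seen in
#' fewer than `min_cells_per_gene` cells are dropped after cell filtering.
#'
#' @param max_mito_frac Mito-fraction cutoff (strict `>`); `NA` disables.
#' @param max_total_umi Doublet cutoff on total UMIs (`>=` removes).
#' @param max_genes_per_cell Doublet cutoff on genes detected (`>=` removes).
#' @param min_cells_per_gene Minimum cells a gene must appear in.
#' @param mad_cutoff Per-cluster MAD multiple for [mad_outlier_filter()].
#' @param scale_factor Normalization scale for [normalize_log()].
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_mito_frac = 0.10,
                          max_total_umi = 50000,
                          max_genes_per_cell = 6000,
                          min_cells_per_gene = 100,
                          mad_cutoff = 5,
                          scale_factor = 10000) {
  t <- list(max_mito_frac = max_mito_frac, max_total_umi = max_total_umi,
            max_genes_per_cell = max_genes_per_cell,
            min_cells_per_gene = min_cells_per_gene,
            mad_cutoff = mad_cutoff, scale_factor = scale_factor)
  if (!is.na(t$max_mito_frac) &&
      (t$max_mito_frac <= 0 || t$max_mito_frac > 1)) {
    stop("max_mito_frac must be in (0, 1] or NA")
  }
  for (f in c("max_total_umi", "max_genes_per_cell", "min_cells_per_gene",
              "mad_cutoff", "scale_factor")) {
    if (t[[f]] <= 0) stop("'", f, "' must be positive")
  }
  class(t) <- "qc_thresholds"
  t
}

# Mito flags: explicit logical vector, else rowData(sce)$is_mito, else
# gene-name prefix.
mito_flags <- function(counts, mito_genes, mito_prefix) {
  if (!is.null(mito_genes)) {
    if (is.logical(mito_genes)) return(mito_genes)
    return(rownames(counts) %in% mito_genes)
  }
  if (is(counts, "SummarizedExperiment")) {
    rd <- SummarizedExperiment::rowData(counts)
    if ("is_mito" %in% colnames(rd)) return(rd$is_mito)
  }
  if (!is.null(rownames(counts))) {
    return(startsWith(rownames(counts), mito_prefix))
  }
  NULL
}

#' Filter low-quality cells, then sparsely expressed genes
#'
#' Applies the three cell rules of [qc_thresholds()] and then the gene
#' rule, in that order. The removal tally is attached as a `qc_log`
#' attribute (metadata entry for SingleCellExperiment input).
#'
#' @param counts Genes x cells integer matrix or SingleCellExperiment with
#'   a `counts` assay.
#' @param thresholds A [qc_thresholds()].
#' @param mito_genes Optional mito-gene names or per-gene logical; defaults
#'   to `rowData(sce)$is_mito` or the `mito_prefix` on rownames.
#' @param mito_prefix Gene-name prefix marking mitochondrial genes.
#' @return The filtered object, same class as the input.
#' @export
filter_cells_genes <- function(counts, thresholds = qc_thresholds(),
                               mito_genes = NULL, mito_prefix = "MT-") {
  t <- thresholds
  m <- get_matrix(counts, "counts")
  total <- Matrix::colSums(m)
  n_genes_cell <- Matrix::colSums(m > 0)

  keep <- rep(TRUE, ncol(m))
  mito_removed <- 0L
  if (!is.na(t$max_mito_frac)) {
    flags <- mito_flags(counts, mito_genes, mito_prefix)
    if (is.null(flags) || !any(flags)) {
      stop("no mitochondrial gene annotation found; pass 'mito_genes' or ",
           "disable the rule with max_mito_frac = NA")
    }
    mito_frac <- Matrix::colSums(m[flags, , drop = FALSE]) / pmax(total, 1)
    bad_mito <- mito_frac > t$max_mito_frac
    mito_removed <- sum(bad_mito)
    keep <- keep & !bad_mito
  }
  bad_umi <- total >= t$max_total_umi
  bad_ngene <- n_genes_cell >= t$max_genes_per_cell
  keep <- keep & !bad_umi & !bad_ngene

  m2 <- m[, keep, drop = FALSE]
  gene_keep <- Matrix::rowSums(m2 > 0) >= t$min_cells_per_gene
  log <- list(cells_in = ncol(m), cells_removed_mito = mito_removed,
              cells_removed_umi = sum(bad_umi),
              cells_removed_ngene = sum(bad_ngene),
              cells_out = sum(keep),
              genes_in = nrow(m), genes_removed = sum(!gene_keep),
              genes_out = sum(gene_keep))

  if (is(counts, "SummarizedExperiment")) {
    out <- counts[gene_keep, keep]
    S4Vectors::metadata(out)$qc_log <- log
  } else {
    out <- m[gene_keep, keep, drop = FALSE]
    attr(out, "qc_log") <- log
  }
  out
}

#' Log-normalize counts to relative expression
#'
#' Each count is divided by the cell's total, scaled by `scale_factor`
#' (counts per 10k by default) and log1p-transformed. Totals are computed
#' before normalization and kept (as attribute / colData) so the transform
#' is invertible.
#'
#' @param counts Genes x cells matrix or SingleCellExperiment.
#' @param scale_factor Counts scale (default 10,000).
#' @return Same class as input; SingleCellExperiment gains a `lognorm`
#'   assay, a matrix gains a `total_umi` attribute.
#' @export
normalize_log <- function(counts, scale_factor = 10000) {
  m <- get_matrix(counts, "counts")
  total <- Matrix::colSums(m)
  if (any(total == 0)) {
    stop("zero-total cell(s): ",
         paste(head(colnames(m)[total == 0] %||%
                      which(total == 0), 5), collapse = ", "))
  }
  norm <- log1p(sweep(as_dense(m), 2, total, "/") * scale_factor)
  if (is(counts, "SummarizedExperiment")) {
    SummarizedExperiment::assay(counts, "lognorm") <- norm
    counts$total_umi <- total
    counts
  } else {
    attr(norm, "total_umi") <- total
    attr(norm, "scale_factor") <- scale_factor
    norm
  }
}

#' Parameters for highly variable gene selection
#'
#' @param min_mean,max_mean Open-interval bounds on the de-logged mean.
#' @param min_disp Minimum binned-z-scored dispersion.
#' @param n_bins Number of equal-frequency mean bins.
#' @return List of class `hvg_params`.
#' @export
hvg_params <- function(min_mean = 0.0125, max_mean = 3, min_disp = 0.5,
                       n_bins = 20L) {
  if (min_mean >= max_mean) stop("min_mean must be < max_mean")
  structure(list(min_mean = min_mean, max_mean = max_mean,
                 min_disp = min_disp, n_bins = as.integer(n_bins)),
            class = "hvg_params")
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Mean and dispersion (variance/mean) are computed on the de-logged
#' (`expm1`) scale; dispersions are z-scored within `n_bins`
#' equal-frequency bins of the mean; genes pass when their mean lies in
#' `(min_mean, max_mean)` and their normalized dispersion is at least
#' `min_disp`. Returned in input gene order.
#'
#' @param norm Log-normalized genes x cells matrix (or SCE with a
#'   `lognorm` assay).
#' @param params A [hvg_params()].
#' @return Character vector of selected gene names (indices if unnamed).
#' @export
select_hvg <- function(norm, params = hvg_params()) {
  x <- as_dense(get_matrix(norm, "lognorm"))
  d <- expm1(x)
  mu <- rowMeans(d)
  v <- apply(d, 1, var)
  disp <- ifelse(mu > 0, v / mu, NA_real_)

  n_bins <- params$n_bins
  ok <- is.finite(disp)
  if (sum(ok) < n_bins) {
    n_bins <- max(1L, sum(ok))
    warning("fewer finite-dispersion genes than bins; reducing to ",
            n_bins, " bins")
  }
  z <- rep(NA_real_, length(mu))
  if (any(ok)) {
    br <- unique(quantile(mu[ok], probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- if (length(br) < 2L) {
      factor(rep("all", sum(ok)))
    } else {
      cut(mu[ok], breaks = br, include.lowest = TRUE)
    }
    zs <- ave(disp[ok], bin, FUN = function(y) {
      s <- sd(y)
      if (!is.finite(s) || s == 0) rep(0, length(y)) else (y - mean(y)) / s
    })
    z[ok] <- zs
  }
  sel <- ok & mu > params$min_mean & mu < params$max_mean &
    z >= params$min_disp
  sel[is.na(sel)] <- FALSE
  out <- rownames(x)[sel] %||% which(sel)
  attr(out, "stats") <- data.frame(
    gene = rownames(x) %||% seq_along(mu), mean = mu, dispersion = disp,
    dispersion_norm = z, selected = sel, row.names = NULL)
  out
}

#' Regress out per-cell covariates from expression
#'
#' Per gene, ordinary least squares of expression on the covariates plus an
#' intercept; the residuals are returned with each gene's mean restored.
#' Collinear covariates are dropped with a warning.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param covariates data.frame (cells x covariates) of finite numerics.
#' @return Residual matrix, same dimensions as the input.
#' @export
regress_out <- function(norm, covariates) {
  x <- as_dense(get_matrix(norm, "lognorm"))
  cv <- as.data.frame(covariates)
  if (nrow(cv) != ncol(x)) stop("covariates must have one row per cell")
  if (!all(vapply(cv, function(c) all(is.finite(c)), logical(1)))) {
    stop("covariates must be finite")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(cv))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping collinear covariate(s): ",
            paste(drop_cols, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
    qrX <- qr(X)
  }
  res <- t(qr.resid(qrX, t(x)))
  res + rowMeans(x)
}

#' Per-cluster MAD outlier filtering of cells
#'
#' Within each cluster and for each QC metric, computes the median `m` and
#' the raw median absolute deviation `MAD = median(|x - m|)` and flags
#' cells with `|x - m| / MAD > mad_cutoff`. A cell flagged in any metric is
#' removed. Degenerate cases are conservative: `MAD = 0` flags nothing, and
#' singleton clusters are kept unfiltered (with a warning). A single pass;
#' no iteration.
#'
#' @param metrics data.frame of per-cell numeric QC metrics (e.g. total
#'   UMIs and mito percentage), one row per cell.
#' @param clusters Cluster label per cell.
#' @param mad_cutoff MAD multiple above which a cell is an outlier.
#' @return Logical vector, TRUE for kept cells (named if metrics has
#'   rownames).
#' @export
mad_outlier_filter <- function(metrics, clusters, mad_cutoff = 5) {
  metrics <- as.data.frame(metrics)
  if (length(clusters) != nrow(metrics)) {
    stop("every cell needs a cluster label")
  }
  keep <- rep(TRUE, nrow(metrics))
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    if (length(idx) == 1L) {
      warning("cluster '", cl, "' has a single cell; kept unfiltered")
      next
    }
    for (metric in names(metrics)) {
      x <- metrics[[metric]][idx]
      m <- median(x)
      mad_raw <- median(abs(x - m))
      if (mad_raw == 0) next
      keep[idx][abs(x - m) / mad_raw > mad_cutoff] <- FALSE
    }
  }
  names(keep) <- rownames(metrics)
  keep
}

#' Score a gene set against expression-matched controls
#'
#' Per cell, the mean expression of the set genes minus the mean expression
#' of a control pool. Controls are drawn per set gene from its
#' average-expression bin (`n_bins` equal-frequency bins over all genes),
#' `ctrl_size` controls per gene without replacement within the bin
#' (falling back to with-replacement when a bin is smaller), excluding set
#' genes from the candidate pool when possible.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param gene_set Character vector of set genes.
#' @param n_bins Expression bins for control matching.
#' @param ctrl_size Controls sampled per set gene.
#' @param seed Integer seed for the control draw.
#' @return Named numeric vector, one score per cell.
#' @export
score_gene_set <- function(norm, gene_set, n_bins = 25L, ctrl_size = 50L,
                           seed = 0L) {
  x <- as_dense(get_matrix(norm, "lognorm"))
  genes <- rownames(x)
  set_genes <- intersect(gene_set, genes)
  if (length(set_genes) == 0L) stop("no gene of the set is in the matrix")

  avg <- rowMeans(x)
  br <- unique(quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) < 2L) {
    factor(rep("all", length(avg)))
  } else {
    cut(avg, breaks = br, include.lowest = TRUE)
  }
  names(bin) <- genes

  ctrl <- with_seed(derive_seed(seed, 11L), {
    picked <- character(0)
    for (g in set_genes) {
      pool <- genes[bin == bin[g]]
      pool_nc <- setdiff(pool, set_genes)
      if (length(pool_nc) > 0) pool <- pool_nc
      if (length(pool) >= ctrl_size) {
        picked <- c(picked, sample(pool, ctrl_size))
      } else {
        picked <- c(picked, sample(pool, ctrl_size, replace = TRUE))
      }
    }
    unique(picked)
  })
  score <- colMeans(x[set_genes, , drop = FALSE]) -
    colMeans(x[ctrl, , drop = FALSE])
  names(score) <- colnames(x)
  score
}

#' Assign cell-cycle phase from S and G2/M gene-set scores
#'
#' Computes both scores with [score_gene_set()]; a cell is called `S` or
#' `G2M` by the larger score when that score is positive, `G1` otherwise.
#' Exact ties with positive score go to `S`.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param s_genes,g2m_genes Phase marker gene sets.
#' @param seed Seed passed to the control draws.
#' @return data.frame with per-cell `s_score`, `g2m_score`, `phase`.
#' @export
assign_cell_cycle <- function(norm, s_genes, g2m_genes, seed = 0L) {
  x <- get_matrix(norm, "lognorm")
  if (length(intersect(s_genes, rownames(x))) == 0L ||
      length(intersect(g2m_genes, rownames(x))) == 0L) {
    stop("S and G2M gene lists must both intersect the matrix genes")
  }
  s <- score_gene_set(x, s_genes, seed = derive_seed(seed, 21L))
  g2m <- score_gene_set(x, g2m_genes, seed = derive_seed(seed, 22L))
  phase <- ifelse(pmax(s, g2m) <= 0, "G1", ifelse(s >= g2m, "S", "G2M"))
  data.frame(s_score = s, g2m_score = g2m, phase = phase,
             row.names = colnames(x) %||% NULL)
}
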