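#' Parameters for differential-distribution calling
#'
#' @param fdr_cutoff BH-adjusted p-value cutoff for any category.
#' @param min_abs_log2fc Minimum |log2 fold change| of nonzero means for a
#'   DE call.
#' @param min_zp_diff Minimum |zero-proportion difference| (percentage
#'   points) for a DZ call.
#' @param jitter_halfwidth Half-width of the uniform jitter applied to
#'   zero-variance genes before testing.
#' @param depth_window Optional `c(low, high)` window of per-cell corrected
#'   totals; cells outside are excluded before testing (off by default).
#' @param apply_fc_to_dm Whether the fold-change gate also applies to DM
#'   calls (off by default; the modality change is the evidence).
#' @param merge_tolerance Log-scale tolerance within which matched mixture
#'   component means are considered the same modality.
#' @param n_permutations Permutations for the DM modality test.
#' @return List of class `dd_params`.
#' @export
dd_params <- function(fdr_cutoff = 0.05, min_abs_log2fc = 1,
                      min_zp_diff = 10, jitter_halfwidth = 0.01,
                      depth_window = NULL, apply_fc_to_dm = FALSE,
                      merge_tolerance = 1, n_permutations = 200L) {
  if (fdr_cutoff <= 0 || min_abs_log2fc < 0 || min_zp_diff < 0) {
    stop("cutoffs must be positive")
  }
  if (jitter_halfwidth <= 0) stop("jitter_halfwidth must be > 0")
  structure(list(fdr_cutoff = fdr_cutoff, min_abs_log2fc = min_abs_log2fc,
                 min_zp_diff = min_zp_diff,
                 jitter_halfwidth = jitter_halfwidth,
                 depth_window = depth_window,
                 apply_fc_to_dm = apply_fc_to_dm,
                 merge_tolerance = merge_tolerance,
                 n_permutations = as.integer(n_permutations)),
            class = "dd_params")
}

#' Depth-correct counts by per-gene negative-binomial regression
#'
#' Per gene, counts are regressed on `log10(total UMIs)` with additive
#' batch offsets (negative binomial with per-gene dispersion estimated
#' from a Poisson fit). The corrected count is the model's prediction at
#' the median depth (batch effects averaged out) plus the cell's Pearson
#' residual rescaled to that prediction's standard deviation, clipped at
#' zero. Genes with all-zero counts pass through as zeros.
#'
#' @param counts Genes x cells integer matrix or SingleCellExperiment.
#' @param batch Optional per-cell batch labels (e.g. donor/sample).
#' @return Dense corrected matrix, same dimensions.
#' @export
correct_depth <- function(counts, batch = NULL) {
  m <- as_dense(get_matrix(counts, "counts"))
  total <- colSums(m)
  if (any(total == 0)) stop("zero-total cell(s) cannot be depth-corrected")
  lt <- log10(total)
  X <- if (sd(lt) < 1e-12) {
    # equal-depth data: nothing to regress out beyond the intercept
    cbind(`(Intercept)` = rep(1, ncol(m)), log_total = 0)[, 1, drop = FALSE]
  } else {
    cbind(`(Intercept)` = 1, log_total = lt)
  }
  if (!is.null(batch)) {
    batch <- factor(batch)
    if (nlevels(batch) > 1L) {
      B <- stats::model.matrix(~batch)[, -1, drop = FALSE]
      X <- cbind(X, B)
    }
  }
  if (qr(X)$rank < ncol(X)) {
    stop("depth/batch design is rank-deficient")
  }
  # prediction covariates at the median depth, batch averaged
  x_med <- colMeans(X)
  if ("log_total" %in% colnames(X)) x_med["log_total"] <- median(lt)

  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (g in seq_len(nrow(m))) {
    y <- m[g, ]
    if (all(y == 0)) next
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::poisson()))
    mu <- fit$fitted.values
    theta <- tryCatch(
      suppressWarnings(MASS::theta.ml(y, mu, limit = 25)),
      error = function(e) Inf)
    theta <- as.numeric(theta)
    if (!is.finite(theta) || theta <= 0) theta <- Inf
    vfun <- function(mm) mm + mm^2 / theta
    pearson <- (y - mu) / sqrt(vfun(mu))
    mu_med <- exp(sum(x_med * fit$coefficients))
    out[g, ] <- pmax(0, mu_med + pearson * sqrt(vfun(mu_med)))
  }
  out
}

# Within-group zero-variance flag: a group has >= 1 nonzero value and all
# its nonzero values are identical.
zero_variance_flag <- function(x, groups) {
  vapply(levels(groups), function(lv) {
    v <- x[groups == lv]
    nz <- v[v != 0]
    length(nz) >= 1L && length(unique(nz)) == 1L
  }, logical(1))
}

#' Jitter genes whose nonzero values have zero within-group variance
#'
#' Genes whose nonzero values are all identical within either group break
#' modality clustering; such genes receive a small uniform perturbation
#' `U(-halfwidth, +halfwidth)` on all of their values (clipped at zero).
#' All other genes are returned untouched (bit-identical).
#'
#' @param matrix Genes x cells numeric matrix.
#' @param groups Two-level factor (or coercible) over cells.
#' @param halfwidth Jitter half-width.
#' @param seed Integer seed.
#' @return The matrix with affected genes perturbed; the set of perturbed
#'   genes is attached as attribute `jittered`.
#' @export
jitter_zero_variance <- function(matrix, groups, halfwidth = 0.01,
                                 seed = 0L) {
  groups <- factor(groups)
  flagged <- apply(matrix, 1, function(x) any(zero_variance_flag(x, groups)))
  if (any(flagged)) {
    with_seed(derive_seed(seed, 31L), {
      idx <- which(flagged)
      noise <- stats::runif(length(idx) * ncol(matrix), -halfwidth,
                            halfwidth)
      matrix[idx, ] <- pmax(0, matrix[idx, , drop = FALSE] +
                              base::matrix(noise, length(idx)))
    })
  }
  attr(matrix, "jittered") <- rownames(matrix)[flagged] %||% which(flagged)
  matrix
}

#' Test differential zero proportion (DZ branch)
#'
#' Per gene, a two-sided Fisher's exact test on the 2x2 table of
#' zero/nonzero status by group, plus the zero-proportion difference in
#' percentage points, `ZP(A) - ZP(B)` where `A` is the first group level.
#'
#' @param matrix Genes x cells numeric matrix.
#' @param groups Two-level factor over cells, each level with >= 2 cells.
#' @return data.frame with `gene`, `p_zero`, `zp_diff`, `zp_a`, `zp_b`.
#' @export
test_dz <- function(matrix, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) stop("both groups need >= 2 cells")
  a <- groups == levels(groups)[1L]
  n_a <- sum(a); n_b <- sum(!a)
  za <- rowSums(matrix[, a, drop = FALSE] == 0)
  zb <- rowSums(matrix[, !a, drop = FALSE] == 0)
  p <- vapply(seq_len(nrow(matrix)), function(g) {
    tab <- base::matrix(c(za[g], n_a - za[g], zb[g], n_b - zb[g]), 2L)
    fisher.test(tab)$p.value
  }, numeric(1))
  data.frame(gene = rownames(matrix) %||% seq_len(nrow(matrix)),
             p_zero = p,
             zp_diff = (za / n_a - zb / n_b) * 100,
             zp_a = za / n_a, zp_b = zb / n_b,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Modality (1 or 2 components) of log nonzero values by BIC-selected
# Gaussian mixture; returns list(G, means).
fit_modality <- function(log_vals) {
  fit <- tryCatch(
    suppressWarnings(Mclust(log_vals, G = 1:2, modelNames = "V",
                            verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(G = 1L, means = mean(log_vals)))
  }
  list(G = fit$G, means = sort(as.numeric(fit$parameters$mean)))
}

# Scalar modality-discrepancy statistic between two groups of log nonzero
# values: the modality difference dominates; with matched modality the
# largest matched-component mean gap is used.
modality_stat <- function(fa, fb) {
  if (fa$G != fb$G) {
    return(1000 + abs(fa$G - fb$G))
  }
  max(abs(fa$means - fb$means))
}

#' Test the nonzero expression distribution (DE/DM branch)
#'
#' Per gene, the log nonzero values of each group are fit with 1- and
#' 2-component Gaussian mixtures selected by BIC. When the modality counts
#' differ, or matched component means differ beyond `merge_tolerance`, the
#' gene is a DM candidate and its p-value comes from a label-permutation
#' test on the modality statistic. When both groups are unimodal the gene
#' is a DE candidate with a two-sided Mann-Whitney p-value. Genes with
#' fewer than 3 nonzero cells in either group get `p = 1`. The log2 fold
#' change is `log2(mean nonzero A / mean nonzero B)`.
#'
#' @param matrix Genes x cells numeric matrix (depth-corrected and
#'   jittered as needed).
#' @param groups Two-level factor over cells.
#' @param params A [dd_params()] (for the merge tolerance and permutation
#'   count).
#' @param seed Integer seed for the permutation draws.
#' @return data.frame with `gene`, `p_nonzero`, `log2_fc`, `modality_a`,
#'   `modality_b`, `dm_candidate`.
#' @export
test_nonzero <- function(matrix, groups, params = dd_params(), seed = 0L) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  a_lab <- levels(groups)[1L]
  res <- vector("list", nrow(matrix))
  for (g in seq_len(nrow(matrix))) {
    x <- matrix[g, ]
    va <- x[groups == a_lab]; vb <- x[groups != a_lab]
    nza <- va[va > 0]; nzb <- vb[vb > 0]
    fc <- if (length(nza) && length(nzb)) {
      log2(mean(nza) / mean(nzb))
    } else NA_real_
    if (length(nza) < 3L || length(nzb) < 3L) {
      res[[g]] <- data.frame(p_nonzero = 1, log2_fc = fc,
                             modality_a = NA_integer_,
                             modality_b = NA_integer_,
                             dm_candidate = FALSE)
      next
    }
    la <- log(nza); lb <- log(nzb)
    fa <- fit_modality(la); fb <- fit_modality(lb)
    dm <- fa$G != fb$G ||
      (fa$G == 2L && modality_stat(fa, fb) > params$merge_tolerance)
    if (dm) {
      t_obs <- modality_stat(fa, fb)
      pooled <- c(la, lb)
      n_a <- length(la)
      p <- with_seed(derive_seed(seed, 41L + g), {
        t_perm <- vapply(seq_len(params$n_permutations), function(i) {
          idx <- sample.int(length(pooled), n_a)
          modality_stat(fit_modality(pooled[idx]),
                        fit_modality(pooled[-idx]))
        }, numeric(1))
        (1 + sum(t_perm >= t_obs)) / (params$n_permutations + 1)
      })
    } else {
      p <- suppressWarnings(wilcox.test(nza, nzb)$p.value)
    }
    res[[g]] <- data.frame(p_nonzero = p, log2_fc = fc,
                           modality_a = fa$G, modality_b = fb$G,
                           dm_candidate = dm)
  }
  out <- do.call(rbind, res)
  out <- cbind(gene = rownames(matrix) %||% seq_len(nrow(matrix)), out)
  rownames(out) <- NULL
  out$gene <- as.character(out$gene)
  out
}

#' Combine DZ and nonzero-branch results into DE/DM/DZ/none calls
#'
#' Both branches are BH-adjusted separately over their tested genes. A
#' gene is DZ when `fdr_zero < fdr_cutoff` and `|zp_diff| >= min_zp_diff`;
#' DM when `fdr_nonzero < fdr_cutoff` and the modality differed (plus the
#' fold-change gate if `apply_fc_to_dm`); DE when `fdr_nonzero <
#' fdr_cutoff`, the gene was not a DM candidate and `|log2_fc| >=
#' min_abs_log2fc`. A gene qualifying in both branches takes the category
#' with the smaller FDR; ties go to DZ.
#'
#' @param dz_results Output of [test_dz()].
#' @param nonzero_results Output of [test_nonzero()].
#' @param params A [dd_params()].
#' @return A DDCall data.frame: `gene`, `category`, `p_nonzero`, `p_zero`,
#'   `fdr_nonzero`, `fdr_zero`, `log2_fc`, `zp_diff`.
#' @export
classify_genes <- function(dz_results, nonzero_results,
                           params = dd_params()) {
  if (!identical(sort(dz_results$gene),
                 sort(as.character(nonzero_results$gene)))) {
    stop("dz and nonzero results must cover the same genes")
  }
  nz <- nonzero_results[match(dz_results$gene, nonzero_results$gene), ]
  fdr_zero <- p.adjust(dz_results$p_zero, method = "BH")
  fdr_nonzero <- p.adjust(nz$p_nonzero, method = "BH")

  dz_hit <- fdr_zero < params$fdr_cutoff &
    abs(dz_results$zp_diff) >= params$min_zp_diff
  dm_hit <- fdr_nonzero < params$fdr_cutoff & nz$dm_candidate
  if (params$apply_fc_to_dm) {
    dm_hit <- dm_hit & !is.na(nz$log2_fc) &
      abs(nz$log2_fc) >= params$min_abs_log2fc
  }
  de_hit <- fdr_nonzero < params$fdr_cutoff & !nz$dm_candidate &
    !is.na(nz$log2_fc) & abs(nz$log2_fc) >= params$min_abs_log2fc
  nonzero_hit <- de_hit | dm_hit

  category <- rep("none", nrow(dz_results))
  both <- dz_hit & nonzero_hit
  category[dz_hit & !nonzero_hit] <- "DZ"
  category[!dz_hit & de_hit] <- "DE"
  category[!dz_hit & dm_hit] <- "DM"
  if (any(both)) {
    dz_wins <- fdr_zero[both] <= fdr_nonzero[both]
    nz_cat <- ifelse(dm_hit[both], "DM", "DE")
    category[both] <- ifelse(dz_wins, "DZ", nz_cat)
  }
  data.frame(gene = dz_results$gene, category = category,
             p_nonzero = nz$p_nonzero, p_zero = dz_results$p_zero,
             fdr_nonzero = fdr_nonzero, fdr_zero = fdr_zero,
             log2_fc = nz$log2_fc, zp_diff = dz_results$zp_diff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full differential-distribution comparison between two cell groups
#'
#' Convenience wrapper: optional depth correction and depth-window cell
#' filter, zero-variance jitter, both test branches, and classification.
#'
#' @param counts Genes x cells count matrix or SingleCellExperiment.
#' @param groups Two-level factor over cells.
#' @param params A [dd_params()].
#' @param batch Optional batch labels for [correct_depth()].
#' @param depth_correct Whether to run [correct_depth()] first.
#' @param seed Integer seed.
#' @return A DDCall data.frame (see [classify_genes()]).
#' @export
dd_test <- function(counts, groups, params = dd_params(), batch = NULL,
                    depth_correct = TRUE, seed = 0L) {
  m <- as_dense(get_matrix(counts, "counts"))
  groups <- factor(groups)
  if (depth_correct) m <- correct_depth(m, batch = batch)
  if (!is.null(params$depth_window)) {
    tot <- colSums(m)
    keep <- tot >= params$depth_window[1] & tot <= params$depth_window[2]
    m <- m[, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
    if (nlevels(groups) != 2L) stop("depth window removed a whole group")
  }
  m <- jitter_zero_variance(m, groups, params$jitter_halfwidth, seed)
  dz <- test_dz(m, groups)
  nz <- test_nonzero(m, groups, params, seed)
  classify_genes(dz, nz, params)
}
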