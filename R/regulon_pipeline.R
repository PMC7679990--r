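#' Construct a regulon
#'
#' A regulon is a driving transcription factor, a sign (`+` activating /
#' `-` repressive regulatory interaction) and a non-empty target-gene set.
#' After merged discovery each target carries `Npred`, the number of
#' train/test discovery iterations that supported it.
#'
#' @param tf TF gene identifier.
#' @param sign "+" or "-".
#' @param targets Character vector of target genes (must not contain `tf`).
#' @param npred Optional integer vector parallel to `targets`.
#' @param active_states Optional states in which the regulon is active
#'   (used by the simulator's truth records).
#' @param n_iterations_found Number of discovery iterations in which a
#'   regulon with this (TF, sign) was found.
#' @return A list of class `regulon`.
#' @export
regulon <- function(tf, sign, targets, npred = NULL,
                    active_states = NULL, n_iterations_found = 1L) {
  if (!sign %in% c("+", "-")) stop("sign must be '+' or '-'")
  targets <- as.character(targets)
  if (length(targets) == 0L) stop("targets must be non-empty")
  if (tf %in% targets) stop("tf must not be among its own targets")
  if (!is.null(npred) && length(npred) != length(targets)) {
    stop("npred must be parallel to targets")
  }
  structure(list(tf = tf, sign = sign, targets = targets,
                 npred = npred %||% rep(1L, length(targets)),
                 active_states = active_states,
                 n_iterations_found = as.integer(n_iterations_found)),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("regulon %s(%s): %d targets (found in %d iteration%s)\n",
              x$tf, x$sign, length(x$targets), x$n_iterations_found,
              if (x$n_iterations_found == 1L) "" else "s"))
  invisible(x)
}

regulon_id <- function(r) paste0(r$tf, "(", r$sign, ")")

#' Cross-validated discovery parameters
#'
#' Defaults follow the workflow's conventions: a 70/30 stratified
#' train/test split, a `p <= 0.001` reproducibility gate on the
#' train-vs-test correlation of per-cell-type mean regulon scores, 10
#' discovery iterations, a linear-model filter fit 100 times on 600
#' sampled cells per cell type retaining mean R-squared >= 0.5, an
#' expression-support filter (mean score in some cell type above the
#' regulon's 70th score percentile while the TF has > 96% zeros), and a
#' TF-correlation filter removing regulons with Pearson r < -0.8 to their
#' TF's expression.
#'
#' @param train_frac Training fraction of the balanced matrix.
#' @param cv_p_cutoff Retention p-value cutoff for the reproducibility gate.
#' @param n_iter Number of independent discovery iterations.
#' @param n_cells_lm Cells sampled per cell type for each linear-model fit.
#' @param n_fits_lm Number of linear-model fits per regulon.
#' @param r2_min Minimum mean R-squared to retain a regulon.
#' @param pct_threshold Percentile (of the regulon's all-cell score
#'   distribution) used by the expression-support filter.
#' @param tf_zero_frac TF zero-fraction above which high scores are
#'   considered unsupported (strict `>`).
#' @param tf_corr_min Regulons with score-vs-TF-expression correlation
#'   strictly below this are removed.
#' @param balanced_n Cells sampled per cell type for discovery.
#' @param top_n_targets Candidate targets per TF by absolute correlation.
#' @param sign_threshold Minimum |r| for a signed edge to survive.
#' @param min_targets Minimum motif-supported targets for a regulon.
#' @param top_fraction Fraction of the gene ranking used by AUC scoring.
#' @param noise_halfwidth Half-width of the zero-count noise injection.
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `cv_params`.
#' @export
cv_params <- function(train_frac = 0.70, cv_p_cutoff = 0.001, n_iter = 10L,
                      n_cells_lm = 600L, n_fits_lm = 100L, r2_min = 0.5,
                      pct_threshold = 70, tf_zero_frac = 0.96,
                      tf_corr_min = -0.8, balanced_n = 100L,
                      top_n_targets = 150L, sign_threshold = 0.03,
                      min_targets = 10L, top_fraction = 0.05,
                      noise_halfwidth = 0.01, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  if (cv_p_cutoff <= 0 || cv_p_cutoff > 1) stop("invalid cv_p_cutoff")
  structure(list(train_frac = train_frac, cv_p_cutoff = cv_p_cutoff,
                 n_iter = as.integer(n_iter),
                 n_cells_lm = as.integer(n_cells_lm),
                 n_fits_lm = as.integer(n_fits_lm), r2_min = r2_min,
                 pct_threshold = pct_threshold,
                 tf_zero_frac = tf_zero_frac, tf_corr_min = tf_corr_min,
                 balanced_n = as.integer(balanced_n),
                 top_n_targets = as.integer(top_n_targets),
                 sign_threshold = sign_threshold,
                 min_targets = as.integer(min_targets),
                 top_fraction = top_fraction,
                 noise_halfwidth = noise_halfwidth,
                 seed = as.integer(seed)),
            class = "cv_params")
}

#' Sample equal numbers of cells per cell type
#'
#' Draws `n = min(n_per_type, smallest type size)` cells from every type
#' without replacement, so differences in type abundance cannot bias
#' downstream correlation structure.
#'
#' @param labels Cell-type label per cell.
#' @param n_per_type Requested cells per type.
#' @param seed Integer seed.
#' @return Integer vector of selected cell indices (sorted).
#' @export
balanced_sample <- function(labels, n_per_type, seed = 0L) {
  labels <- as.character(labels)
  sizes <- table(labels)
  n <- min(n_per_type, min(sizes))
  with_seed(derive_seed(seed, 51L), {
    sort(unlist(lapply(split(seq_along(labels), labels), function(idx) {
      sample(idx, n)
    }), use.names = FALSE))
  })
}

#' Replace zero entries by small uniform noise
#'
#' Every zero entry of the (normalized) matrix is replaced by a draw from
#' `U(-halfwidth, +halfwidth)`; nonzero entries are untouched. This lets
#' correlation-based target inference see repressed genes instead of a
#' constant zero block.
#'
#' @param matrix Numeric matrix.
#' @param halfwidth Noise half-width.
#' @param seed Integer seed.
#' @return Matrix with zeros replaced.
#' @export
inject_zero_noise <- function(matrix, halfwidth = 0.01, seed = 0L) {
  z <- matrix == 0
  if (any(z)) {
    with_seed(derive_seed(seed, 52L), {
      matrix[z] <- stats::runif(sum(z), -halfwidth, halfwidth)
    })
  }
  matrix
}

#' Infer signed TF-target edges by Pearson correlation
#'
#' For each TF, Pearson correlation against every other gene over all
#' cells of the (noise-injected) matrix; the `top_n_targets` genes by
#' absolute correlation are kept as candidates and signed: `+` when `r >
#' sign_threshold`, `-` when `r < -sign_threshold`, dropped otherwise.
#'
#' @param matrix Genes x cells numeric matrix.
#' @param tf_list TF gene names (must be rows of the matrix).
#' @param top_n_targets Candidates per TF.
#' @param sign_threshold Dead zone around zero correlation.
#' @return data.frame with `tf`, `gene`, `r`, `sign`.
#' @export
infer_links <- function(matrix, tf_list, top_n_targets = 150L,
                        sign_threshold = 0.03) {
  tf_list <- intersect(tf_list, rownames(matrix))
  if (length(tf_list) == 0L) stop("no TF of tf_list is in the matrix")
  tx <- t(matrix)
  tf_sd <- apply(tx[, tf_list, drop = FALSE], 2, sd)
  if (any(tf_sd == 0)) {
    warning("skipping constant TF(s): ",
            paste(tf_list[tf_sd == 0], collapse = ", "))
    tf_list <- tf_list[tf_sd > 0]
    if (length(tf_list) == 0L) {
      return(data.frame(tf = character(), gene = character(),
                        r = numeric(), sign = character()))
    }
  }
  cc <- safe_cor(tx[, tf_list, drop = FALSE], tx)
  out <- lapply(tf_list, function(tf) {
    r <- cc[tf, ]
    r <- r[names(r) != tf & !is.na(r)]
    r <- r[order(-abs(r))][seq_len(min(top_n_targets, length(r)))]
    keep <- abs(r) > sign_threshold
    r <- r[keep]
    data.frame(tf = rep(tf, length(r)), gene = names(r), r = unname(r),
               sign = ifelse(r > 0, "+", "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Prune candidate edges by motif support and build signed regulons
#'
#' Keeps edges whose (TF, gene) pair appears in the motif-annotation
#' table, splits each TF's surviving edges by sign into separate
#' activating and repressive regulons, and drops regulons with fewer than
#' `min_targets` targets. TFs absent from the motif table lose all their
#' regulons (recorded in the `dropped_tfs` attribute).
#'
#' @param edges Edge table from [infer_links()].
#' @param motif_table data.frame with columns `tf`, `gene`.
#' @param min_targets Minimum surviving targets per regulon.
#' @return List of [regulon()] objects.
#' @export
prune_by_motif <- function(edges, motif_table, min_targets = 10L) {
  if (nrow(edges) == 0L) return(structure(list(), dropped_tfs = character()))
  motif_key <- paste(motif_table$tf, motif_table$gene)
  dropped <- setdiff(unique(edges$tf), unique(motif_table$tf))
  supported <- edges[paste(edges$tf, edges$gene) %in% motif_key, ,
                     drop = FALSE]
  regs <- list()
  if (nrow(supported) > 0L) {
    for (grp in split(supported, paste(supported$tf, supported$sign))) {
      if (nrow(grp) < min_targets) next
      regs[[length(regs) + 1L]] <-
        regulon(tf = grp$tf[1], sign = grp$sign[1], targets = grp$gene)
    }
  }
  structure(regs, dropped_tfs = dropped)
}

# Per-cell gene ranking by decreasing expression, ties broken by a seeded
# random permutation fixed per call. Returns a genes x cells integer matrix
# of ranks (1 = highest expression).
rank_cells <- function(matrix, seed = 0L) {
  n <- nrow(matrix)
  tie <- with_seed(derive_seed(seed, 53L), sample.int(n))
  ranks <- matrix(0L, n, ncol(matrix), dimnames = dimnames(matrix))
  for (j in seq_len(ncol(matrix))) {
    ord <- order(-matrix[, j], tie)
    ranks[ord, j] <- seq_len(n)
  }
  ranks
}

# Recovery-curve AUC from a precomputed rank matrix for one target set.
auc_from_ranks <- function(ranks, targets, top_fraction) {
  n <- nrow(ranks)
  k <- ceiling(top_fraction * n)
  idx <- which(rownames(ranks) %in% targets)
  if (length(idx) == 0L) stop("no regulon gene present in the matrix")
  m <- length(idx)
  rr <- ranks[idx, , drop = FALSE]
  contrib <- pmax(k - rr + 1L, 0L)
  auc_max <- sum(k - seq_len(min(m, k)) + 1L)
  colSums(contrib) / auc_max
}

#' AUC recovery-curve activity score of a regulon
#'
#' Per cell, all genes are ranked by decreasing expression (ties broken by
#' a seeded random permutation fixed per run). With threshold `k =
#' ceiling(top_fraction * n_genes)`, the recovery curve counts regulon
#' genes found at each rank `1..k`; its step-sum area, divided by the
#' maximum achievable (all regulon genes at the very top), gives a score
#' in `[0, 1]`. Repressive regulons are scored on the same ranking, so a
#' high score always means "targets are expressed".
#'
#' @param matrix Normalized genes x cells matrix.
#' @param reg A [regulon()] (or a character vector of target genes).
#' @param top_fraction Fraction of the ranking considered.
#' @param seed Integer seed for the tie-break permutation.
#' @return Named numeric vector of per-cell scores in `[0, 1]`.
#' @export
auc_score <- function(matrix, reg, top_fraction = 0.05, seed = 0L) {
  targets <- if (inherits(reg, "regulon")) reg$targets else as.character(reg)
  ranks <- rank_cells(as_dense(matrix), seed)
  auc_from_ranks(ranks, targets, top_fraction)
}

#' Score many regulons on one matrix (shared ranking)
#'
#' @param matrix Normalized genes x cells matrix.
#' @param regulons List of [regulon()] objects.
#' @param top_fraction Fraction of the ranking considered.
#' @param seed Integer seed for the tie-break permutation.
#' @return Cells x regulons score matrix, columns named `TF(sign)`.
#' @export
auc_score_matrix <- function(matrix, regulons, top_fraction = 0.05,
                             seed = 0L) {
  ranks <- rank_cells(as_dense(matrix), seed)
  scores <- vapply(regulons, function(r) {
    auc_from_ranks(ranks, r$targets, top_fraction)
  }, numeric(ncol(matrix)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = ncol(matrix))
  dimnames(scores) <- list(colnames(matrix),
                           vapply(regulons, regulon_id, character(1)))
  scores
}

#' Reproducibility gate on train/test mean score vectors
#'
#' For each regulon, Pearson correlation between its per-cell-type mean
#' scores in the training and test sets (one point per cell type) with a
#' two-sided t-distribution p-value on `n - 2` degrees of freedom.
#' Regulons with undefined correlation (zero variance) are discarded as
#' failed reproducibility.
#'
#' @param train_means,test_means Cell types x regulons matrices of mean
#'   scores.
#' @param p_cutoff Retain regulons with `p <= p_cutoff`.
#' @return data.frame with `regulon`, `r`, `p`, `retained`.
#' @export
cv_gate <- function(train_means, test_means, p_cutoff = 0.001) {
  stopifnot(nrow(train_means) == nrow(test_means),
            ncol(train_means) == ncol(test_means))
  n <- nrow(train_means)
  if (n < 3L) stop("the correlation gate needs >= 3 cell types")
  res <- lapply(seq_len(ncol(train_means)), function(j) {
    r <- suppressWarnings(cor(train_means[, j], test_means[, j]))
    if (is.na(r)) {
      return(data.frame(r = NA_real_, p = NA_real_, retained = FALSE))
    }
    r <- min(max(r, -1), 1)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    data.frame(r = r, p = p, retained = p <= p_cutoff)
  })
  out <- do.call(rbind, res)
  out <- cbind(regulon = colnames(train_means) %||%
                 seq_len(ncol(train_means)), out)
  rownames(out) <- NULL
  out
}

#' One cross-validated discovery round
#'
#' Splits the balanced matrix stratified by cell type into training
#' (`train_frac`) and test sets, discovers candidate regulons on the
#' training set ([infer_links()] then [prune_by_motif()]), scores both
#' sets, and retains regulons passing [cv_gate()] at `cv_p_cutoff`.
#'
#' @param matrix Noise-injected normalized genes x cells matrix (balanced
#'   across cell types).
#' @param labels Cell-type label per cell (>= 3 types).
#' @param motif_table Motif-annotation table (`tf`, `gene`).
#' @param params A [cv_params()].
#' @param seed Integer seed for the split and score tie-breaks.
#' @param tf_list TF universe; defaults to the motif table's TFs.
#' @return List with `regulons` (retained), `gate` (the [cv_gate()]
#'   table), and `candidates`.
#' @export
crossvalidate <- function(matrix, labels, motif_table, params = cv_params(),
                          seed = 0L, tf_list = NULL) {
  labels <- as.character(labels)
  types <- unique(labels)
  if (length(types) < 3L) stop("need >= 3 cell types")
  tf_list <- tf_list %||% unique(motif_table$tf)

  train_idx <- with_seed(derive_seed(seed, 54L), {
    sort(unlist(lapply(split(seq_along(labels), labels), function(idx) {
      sample(idx, max(1L, round(params$train_frac * length(idx))))
    }), use.names = FALSE))
  })
  test_idx <- setdiff(seq_along(labels), train_idx)

  edges <- infer_links(matrix[, train_idx, drop = FALSE], tf_list,
                       params$top_n_targets, params$sign_threshold)
  cands <- prune_by_motif(edges, motif_table, params$min_targets)
  if (length(cands) == 0L) {
    return(list(regulons = list(),
                gate = data.frame(regulon = character(), r = numeric(),
                                  p = numeric(), retained = logical()),
                candidates = cands))
  }
  tr_scores <- auc_score_matrix(matrix[, train_idx, drop = FALSE], cands,
                                params$top_fraction,
                                derive_seed(seed, 55L))
  te_scores <- auc_score_matrix(matrix[, test_idx, drop = FALSE], cands,
                                params$top_fraction,
                                derive_seed(seed, 56L))
  mean_by_type <- function(s, labs) {
    do.call(rbind, lapply(types, function(ty) {
      colMeans(s[labs == ty, , drop = FALSE])
    }))
  }
  gate <- cv_gate(mean_by_type(tr_scores, labels[train_idx]),
                  mean_by_type(te_scores, labels[test_idx]),
                  params$cv_p_cutoff)
  list(regulons = cands[gate$retained], gate = gate, candidates = cands)
}

#' Merged multi-iteration regulon discovery with activity scoring
#'
#' Runs `n_iter` independent iterations of balanced sampling, zero-count
#' noise injection and cross-validated discovery; surviving regulons are
#' merged by (TF, sign) with target sets unioned and `Npred(target)` = the
#' number of iterations containing the target. Each iteration's retained
#' regulons are scored on the whole dataset, and the final activity of a
#' merged regulon is the mean of its iterations' score vectors.
#'
#' @param norm Log-normalized genes x cells matrix of the full dataset.
#' @param labels Cell-type label per cell.
#' @param motif_table Motif-annotation table (`tf`, `gene`).
#' @param params A [cv_params()]; `params$seed` drives everything.
#' @param tf_list TF universe; defaults to the motif table's TFs.
#' @return List with `regulons` (merged, with `npred` and
#'   `n_iterations_found`), `activity` (cells x regulons matrix), and
#'   `iterations` (per-iteration gate tables).
#' @export
run_discovery <- function(norm, labels, motif_table, params = cv_params(),
                          tf_list = NULL) {
  norm <- as_dense(norm)
  labels <- as.character(labels)
  tf_list <- tf_list %||% unique(motif_table$tf)
  master <- params$seed

  iter_regs <- vector("list", params$n_iter)
  iter_scores <- vector("list", params$n_iter)
  gates <- vector("list", params$n_iter)
  full_ranks_seed <- derive_seed(master, 60L)
  for (it in seq_len(params$n_iter)) {
    it_seed <- derive_seed(master, 100L + it)
    idx <- balanced_sample(labels, params$balanced_n, it_seed)
    sub <- inject_zero_noise(norm[, idx, drop = FALSE],
                             params$noise_halfwidth, it_seed)
    cvr <- crossvalidate(sub, labels[idx], motif_table, params, it_seed,
                         tf_list)
    iter_regs[[it]] <- cvr$regulons
    gates[[it]] <- cvr$gate
    if (length(cvr$regulons) > 0L) {
      iter_scores[[it]] <- auc_score_matrix(norm, cvr$regulons,
                                            params$top_fraction,
                                            full_ranks_seed)
    }
  }

  ids <- unlist(lapply(iter_regs, function(rs) {
    vapply(rs, regulon_id, character(1))
  }))
  if (length(ids) == 0L) {
    message("no regulon survived cross-validation")
    return(list(regulons = list(),
                activity = matrix(numeric(0), nrow = ncol(norm), ncol = 0,
                                  dimnames = list(colnames(norm), NULL)),
                iterations = gates))
  }
  merged <- list()
  activity <- matrix(0, ncol(norm), 0,
                     dimnames = list(colnames(norm), NULL))
  for (id in unique(ids)) {
    hits <- list(); svecs <- list()
    for (it in seq_len(params$n_iter)) {
      rs <- iter_regs[[it]]
      if (length(rs) == 0L) next
      j <- which(vapply(rs, regulon_id, character(1)) == id)
      if (length(j) == 0L) next
      hits[[length(hits) + 1L]] <- rs[[j[1]]]
      svecs[[length(svecs) + 1L]] <- iter_scores[[it]][, j[1]]
    }
    all_targets <- unlist(lapply(hits, function(r) r$targets))
    npred_tab <- table(all_targets)
    targets <- names(npred_tab)
    merged[[length(merged) + 1L]] <- regulon(
      tf = hits[[1]]$tf, sign = hits[[1]]$sign, targets = targets,
      npred = as.integer(npred_tab),
      n_iterations_found = length(hits))
    activity <- cbind(activity, rowMeans(do.call(cbind, svecs)))
    colnames(activity)[ncol(activity)] <- id
  }
  list(regulons = merged, activity = activity, iterations = gates)
}

# R-squared of score ~ cell type (one-way ANOVA identity), per column of a
# cells x regulons score matrix; constant columns yield 0.
r2_by_type <- function(scores, labels) {
  grand <- colMeans(scores)
  ss_tot <- colSums(sweep(scores, 2, grand)^2)
  ss_b <- rep(0, ncol(scores))
  for (ty in unique(labels)) {
    sel <- labels == ty
    mu_t <- colMeans(scores[sel, , drop = FALSE])
    ss_b <- ss_b + sum(sel) * (mu_t - grand)^2
  }
  ifelse(ss_tot > 0, ss_b / ss_tot, 0)
}

#' Linear-model filter: does activity vary between cell types?
#'
#' Fits `score ~ cell type` (ordinary least squares on one-hot labels)
#' `n_fits_lm` times per regulon, each time on a balanced subsample of
#' `n_cells_lm` cells per cell type, and records the coefficient of
#' determination. Regulons whose mean R-squared falls below `r2_min` do
#' not separate cell types and are removed. A constant score has
#' R-squared 0 by definition.
#'
#' @param activity Cells x regulons score matrix.
#' @param labels Cell-type label per cell.
#' @param params A [cv_params()].
#' @param seed Integer seed for the subsampling.
#' @return data.frame with `regulon`, `mean_r2`, `retained`.
#' @export
filter_linear_model <- function(activity, labels, params = cv_params(),
                                seed = 0L) {
  labels <- as.character(labels)
  r2 <- matrix(0, params$n_fits_lm, ncol(activity))
  for (f in seq_len(params$n_fits_lm)) {
    idx <- balanced_sample(labels, params$n_cells_lm,
                           derive_seed(seed, 200L + f))
    r2[f, ] <- r2_by_type(activity[idx, , drop = FALSE], labels[idx])
  }
  mean_r2 <- colMeans(r2)
  data.frame(regulon = colnames(activity) %||% seq_len(ncol(activity)),
             mean_r2 = mean_r2, retained = mean_r2 >= params$r2_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression-support filter
#'
#' A regulon is removed when its mean score in some cell type exceeds the
#' 70th percentile of its own all-cell score distribution while its TF's
#' expression is zero in more than `tf_zero_frac` of cells — high
#' apparent activity with no detectable TF. TFs missing from the matrix
#' remove their regulons (no evidence at all).
#'
#' @param activity Cells x regulons score matrix.
#' @param regulons List of [regulon()] parallel to the columns.
#' @param norm Normalized genes x cells expression matrix.
#' @param labels Cell-type label per cell.
#' @param pct_threshold Score percentile (0-100).
#' @param tf_zero_frac Zero-fraction cutoff (strict `>` removes).
#' @return data.frame with `regulon`, `tf_zero_frac`, `max_type_mean`,
#'   `score_pctl`, `retained`.
#' @export
filter_expression_support <- function(activity, regulons, norm, labels,
                                      pct_threshold = 70,
                                      tf_zero_frac = 0.96) {
  labels <- as.character(labels)
  types <- unique(labels)
  res <- lapply(seq_along(regulons), function(j) {
    r <- regulons[[j]]
    s <- activity[, j]
    pctl <- quantile(s, pct_threshold / 100, names = FALSE)
    type_means <- vapply(types, function(ty) mean(s[labels == ty]),
                         numeric(1))
    if (!r$tf %in% rownames(norm)) {
      return(data.frame(regulon = regulon_id(r), tf_zero_frac = NA_real_,
                        max_type_mean = max(type_means), score_pctl = pctl,
                        retained = FALSE))
    }
    zf <- mean(norm[r$tf, ] == 0)
    bad <- any(type_means > pctl) && zf > tf_zero_frac
    data.frame(regulon = regulon_id(r), tf_zero_frac = zf,
               max_type_mean = max(type_means), score_pctl = pctl,
               retained = !bad)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' TF-correlation filter
#'
#' Removes regulons whose per-cell activity correlates strongly negatively
#' (Pearson `r < tf_corr_min`, default -0.8) with their TF's normalized
#' expression. Undefined correlations (constant score or TF vector) are
#' kept: they carry no evidence of anti-correlation.
#'
#' @param activity Cells x regulons score matrix.
#' @param regulons List of [regulon()] parallel to the columns.
#' @param norm Normalized genes x cells expression matrix.
#' @param tf_corr_min Removal threshold (strict `<`).
#' @return data.frame with `regulon`, `tf_cor`, `retained`.
#' @export
filter_tf_correlation <- function(activity, regulons, norm,
                                  tf_corr_min = -0.8) {
  res <- lapply(seq_along(regulons), function(j) {
    r <- regulons[[j]]
    tf_cor <- if (r$tf %in% rownames(norm)) {
      suppressWarnings(cor(activity[, j], norm[r$tf, ]))
    } else NA_real_
    data.frame(regulon = regulon_id(r), tf_cor = tf_cor,
               retained = is.na(tf_cor) || tf_cor >= tf_corr_min)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Apply the three post-discovery regulon filters
#'
#' Runs [filter_linear_model()], [filter_expression_support()] and
#' [filter_tf_correlation()] and keeps regulons retained by all three.
#'
#' @param discovery Output of [run_discovery()].
#' @param norm Normalized genes x cells matrix of the full dataset.
#' @param labels Cell-type label per cell.
#' @param params A [cv_params()].
#' @param seed Integer seed for the linear-model subsampling.
#' @return List with `regulons`, `activity` (filtered columns) and
#'   `report` (per-regulon decisions from all three filters).
#' @export
apply_regulon_filters <- function(discovery, norm, labels,
                                  params = cv_params(), seed = 0L) {
  regs <- discovery$regulons
  act <- discovery$activity
  if (length(regs) == 0L) {
    return(list(regulons = regs, activity = act,
                report = data.frame(regulon = character())))
  }
  norm <- as_dense(norm)
  lm_f <- filter_linear_model(act, labels, params, seed)
  ex_f <- filter_expression_support(act, regs, norm, labels,
                                    params$pct_threshold,
                                    params$tf_zero_frac)
  co_f <- filter_tf_correlation(act, regs, norm, params$tf_corr_min)
  keep <- lm_f$retained & ex_f$retained & co_f$retained
  report <- data.frame(regulon = lm_f$regulon, mean_r2 = lm_f$mean_r2,
                       lm_retained = lm_f$retained,
                       tf_zero_frac = ex_f$tf_zero_frac,
                       support_retained = ex_f$retained,
                       tf_cor = co_f$tf_cor,
                       cor_retained = co_f$retained,
                       retained = keep, stringsAsFactors = FALSE)
  list(regulons = regs[keep], activity = act[, keep, drop = FALSE],
       report = report)
}
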