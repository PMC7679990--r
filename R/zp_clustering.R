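#' Zero-proportion profiles of genes across cell states
#'
#' For each requested gene and state, the exact fraction of that state's
#' cells with a zero count — the mRNA detection metric used to compare
#' leukemic and normal differentiation states.
#'
#' @param counts Genes x cells count matrix or SingleCellExperiment.
#' @param state_labels State label per cell.
#' @param genes Genes to profile (default: all).
#' @param states State order for the columns (default: order of first
#'   appearance).
#' @return Genes x states matrix of values in `[0, 1]`.
#' @export
zp_profile <- function(counts, state_labels, genes = NULL, states = NULL) {
  m <- get_matrix(counts, "counts")
  genes <- genes %||% rownames(m)
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes) > 0L) {
    stop("unknown gene(s): ", paste(head(missing_genes, 5), collapse = ", "))
  }
  state_labels <- as.character(state_labels)
  states <- states %||% unique(state_labels)
  missing_states <- setdiff(states, state_labels)
  if (length(missing_states) > 0L) {
    stop("state(s) with no cells: ",
         paste(missing_states, collapse = ", "))
  }
  zp <- vapply(states, function(st) {
    sel <- state_labels == st
    Matrix::rowSums(m[genes, sel, drop = FALSE] == 0) / sum(sel)
  }, numeric(length(genes)))
  if (is.null(dim(zp))) zp <- matrix(zp, nrow = length(genes))
  dimnames(zp) <- list(genes, states)
  zp
}

# Pearson correlation of each profile row against each centroid row,
# NA-safe (constant vectors yield -Inf so they are never preferred).
cor_to_centroids <- function(profiles, centroids) {
  cc <- safe_cor(t(profiles), t(centroids))
  cc[is.na(cc)] <- -Inf
  cc
}

#' K-means with correlation distance (k-centroids clustering)
#'
#' Lloyd-style iteration where each profile joins the centroid with the
#' highest Pearson correlation (distance `1 - r`), and a centroid is the
#' arithmetic mean of its member profiles after row standardization
#' (z-scoring each profile across states). Standardizing before averaging
#' makes the whole procedure exactly invariant to positive affine
#' transforms of any profile — the natural symmetry of correlation
#' distance. Empty clusters are reseeded from the worst-fit profile;
#' iteration stops when assignments stabilize. The best of `n_init`
#' seeded restarts by total within-cluster `1 - r` is returned. Profiles
#' that are constant across states have no defined correlation and are
#' segregated into a `flat` pseudo-cluster (id 0) before clustering.
#'
#' @param profiles Genes x states numeric matrix (e.g. from
#'   [zp_profile()]).
#' @param k Number of clusters.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param n_init Number of random restarts.
#' @param seed Integer seed.
#' @return List of class `zp_kmeans` with `assignments` (named integer;
#'   0 = flat pseudo-cluster), `centroids` (k x states, standardized
#'   scale), `centroids_zp` (k x states, mean of raw member profiles, for
#'   display on the original scale), `withinss` (total within-cluster
#'   `1 - r`), `flat_profiles`.
#' @export
kmeans_correlation <- function(profiles, k = 8L, max_iter = 100L,
                               n_init = 10L, seed = 0L) {
  profiles <- as.matrix(profiles)
  if (k < 2L) stop("k must be >= 2")
  row_sd <- apply(profiles, 1, sd)
  flat <- row_sd == 0 | is.na(row_sd)
  raw <- profiles[!flat, , drop = FALSE]
  work <- t(scale(t(raw))) # row z-score; correlation-equivalent form
  if (nrow(work) < k) stop("k exceeds the number of variable profiles")

  run_once <- function(rs) {
    init <- with_seed(rs, sample.int(nrow(work), k))
    centroids <- work[init, , drop = FALSE]
    assign_prev <- rep(0L, nrow(work))
    for (iter in seq_len(max_iter)) {
      cc <- cor_to_centroids(work, centroids)
      assignment <- max.col(cc, ties.method = "first")
      best_cor <- cc[cbind(seq_len(nrow(work)), assignment)]
      for (cl in seq_len(k)) {
        if (!any(assignment == cl)) {
          worst <- which.min(best_cor)
          assignment[worst] <- cl
          best_cor[worst] <- Inf
        }
      }
      if (identical(assignment, assign_prev)) break
      assign_prev <- assignment
      for (cl in seq_len(k)) {
        centroids[cl, ] <- colMeans(work[assignment == cl, , drop = FALSE])
      }
    }
    cc <- cor_to_centroids(work, centroids)
    assignment <- max.col(cc, ties.method = "first")
    withinss <- sum(1 - cc[cbind(seq_len(nrow(work)), assignment)])
    list(assignment = assignment, centroids = centroids,
         withinss = withinss)
  }

  best <- NULL
  for (i in seq_len(n_init)) {
    cand <- run_once(derive_seed(seed, 300L + i))
    if (is.null(best) || cand$withinss < best$withinss) best <- cand
  }
  assignments <- rep(0L, nrow(profiles))
  assignments[!flat] <- best$assignment
  names(assignments) <- rownames(profiles)
  rownames(best$centroids) <- paste0("cluster", seq_len(k))
  centroids_zp <- do.call(rbind, lapply(seq_len(k), function(cl) {
    colMeans(raw[best$assignment == cl, , drop = FALSE])
  }))
  rownames(centroids_zp) <- paste0("cluster", seq_len(k))
  structure(list(assignments = assignments, centroids = best$centroids,
                 centroids_zp = centroids_zp,
                 withinss = best$withinss,
                 flat_profiles = rownames(profiles)[flat] %||% which(flat),
                 k = k),
            class = "zp_kmeans")
}

#' Mean silhouette width under correlation distance
#'
#' @param profiles Genes x states matrix.
#' @param assignments Cluster id per profile (0s are ignored).
#' @return Mean silhouette over profiles in clusters of size >= 2.
#' @export
silhouette_correlation <- function(profiles, assignments) {
  keep <- assignments > 0
  x <- profiles[keep, , drop = FALSE]
  cl <- assignments[keep]
  d <- 1 - safe_cor(t(x), t(x))
  d[is.na(d)] <- 2
  sil <- vapply(seq_len(nrow(x)), function(i) {
    own <- cl == cl[i]
    if (sum(own) < 2L) return(NA_real_)
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(other) {
      mean(d[i, cl == other])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil, na.rm = TRUE)
}

#' Scan a range of k values
#'
#' Runs [kmeans_correlation()] for each k and reports the total
#' within-cluster correlation distance and the mean silhouette, to guide
#' the choice of k.
#'
#' @param profiles Genes x states matrix.
#' @param k_range Integer vector of k values.
#' @param n_init,max_iter,seed Passed to [kmeans_correlation()].
#' @return data.frame with `k`, `withinss`, `silhouette`.
#' @export
scan_k <- function(profiles, k_range = 6:10, n_init = 10L,
                   max_iter = 100L, seed = 0L) {
  res <- lapply(k_range, function(k) {
    fit <- kmeans_correlation(profiles, k = k, max_iter = max_iter,
                              n_init = n_init, seed = seed)
    data.frame(k = k, withinss = fit$withinss,
               silhouette = silhouette_correlation(profiles,
                                                   fit$assignments))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
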