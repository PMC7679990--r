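# Shared fixtures, built in code. The cached small simulation keeps the
# per-file cost down; everything is deterministic given the seeds below.

.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small_sim)) {
    cfg <- simulation_config(n_states = 6, cells_per_state = 80,
                             n_genes = 600, n_tfs = 12,
                             n_planted_regulons = 6,
                             targets_per_regulon = 15,
                             dd_de_genes = 20, dd_dm_genes = 8,
                             dd_dz_genes = 20, seed = 11)
    .fixture_env$small_sim <- simulate_dataset(cfg)
  }
  .fixture_env$small_sim
}

small_norm <- function() {
  if (is.null(.fixture_env$small_norm)) {
    sim <- small_sim()
    m <- as.matrix(SummarizedExperiment::assay(sim$sce, "counts"))
    .fixture_env$small_norm <- normalize_log(m)
  }
  .fixture_env$small_norm
}

reg_id <- function(r) paste0(r$tf, "(", r$sign, ")")

# Brute-force recovery-curve AUC: walk the ranking cell by cell and sum the
# step curve explicitly. Independent of the package's vectorized path.
brute_auc <- function(expr_matrix, targets, top_fraction, rank_tiebreak) {
  n <- nrow(expr_matrix)
  k <- ceiling(top_fraction * n)
  vapply(seq_len(ncol(expr_matrix)), function(j) {
    ord <- order(-expr_matrix[, j], rank_tiebreak)
    ranked_genes <- rownames(expr_matrix)[ord]
    hits <- cumsum(ranked_genes %in% targets)[seq_len(k)]
    m <- sum(rownames(expr_matrix) %in% targets)
    max_hits <- cumsum(seq_len(n) <= m)[seq_len(k)]
    sum(hits) / sum(max_hits)
  }, numeric(1))
}

# All-pairs interval-membership oracle for peak-to-gene association.
brute_associate <- function(peaks, domains) {
  mid <- floor((peaks$start + peaks$end) / 2)
  lapply(seq_len(nrow(domains)), function(g) {
    which(peaks$chrom == domains$chrom[g] &
            mid >= domains$dom_start[g] & mid < domains$dom_end[g])
  })
}
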