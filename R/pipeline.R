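#' Run the full synthetic-data analysis pipeline
#'
#' End-to-end, deterministic given `seed`: simulate a ground-truthed
#' dataset; QC-filter cells and genes; normalize; select highly variable
#' genes; assign cell-cycle phases; MAD-filter outlier cells per state;
#' run merged cross-validated regulon discovery plus the three post-hoc
#' filters; call differential-distribution categories between the two
#' pivot states; cluster zero-proportion profiles; and validate final
#' regulons against the simulated peak file. All results are written as
#' plain-text files under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param config A [simulation_config()] (its seed is overridden by
#'   `seed`).
#' @param params A [cv_params()] (its seed is overridden by `seed`).
#' @param seed Master seed for every stage.
#' @param dd_max_genes Differential-distribution testing runs on the
#'   planted DD genes plus a random background subsample capped at this
#'   many genes (keeps the mixture fits affordable).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(out_dir, config = simulation_config(),
                         params = cv_params(), seed = 1L,
                         dd_max_genes = 300L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- derive_seed(seed, 1000L)
  params$seed <- derive_seed(seed, 2000L)

  sim <- simulate_dataset(config)
  write_dataset(sim, file.path(out_dir, "dataset"))

  qcd <- filter_cells_genes(sim$sce, qc_thresholds())
  norm_sce <- normalize_log(qcd)
  hvgs <- select_hvg(norm_sce)
  norm <- as_dense(get_matrix(norm_sce, "lognorm"))
  cc <- assign_cell_cycle(norm, sim$truth$s_genes, sim$truth$g2m_genes,
                          seed = derive_seed(seed, 3000L))
  metrics <- data.frame(total_umi = qcd$total_umi,
                        mito_pct = qcd$mito_frac * 100,
                        row.names = colnames(qcd))
  keep <- mad_outlier_filter(metrics, qcd$state, qc_thresholds()$mad_cutoff)
  norm <- norm[, keep, drop = FALSE]
  labels <- qcd$state[keep]
  counts_kept <- as_dense(get_matrix(qcd, "counts"))[, keep, drop = FALSE]

  qc_report <- data.frame(
    barcode = colnames(qcd), state = qcd$state, phase_true = qcd$phase,
    phase_called = cc$phase, total_umi = qcd$total_umi,
    mito_pct = round(qcd$mito_frac * 100, 4), mad_kept = keep)
  write.table(qc_report, file.path(out_dir, "qc_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(hvgs, file.path(out_dir, "hvg.txt"))

  disc <- run_discovery(norm, labels, sim$motifs, params)
  filt <- apply_regulon_filters(disc, norm, labels, params,
                                seed = derive_seed(seed, 4000L))
  write_regulons(filt$regulons, file.path(out_dir, "regulons.json"))
  write_matrix_tsv(filt$activity, file.path(out_dir, "activity.tsv"),
                   id_col = "barcode")
  write.table(filt$report, file.path(out_dir, "filter_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # DD calls between the pivot states recorded in the truth
  pair <- c(sim$truth$dd_genes$state_a[1], sim$truth$dd_genes$state_b[1])
  sel <- labels %in% pair
  dd_gene_pool <- intersect(sim$truth$dd_genes$gene, rownames(counts_kept))
  background <- setdiff(rownames(counts_kept), dd_gene_pool)
  n_bg <- max(0L, dd_max_genes - length(dd_gene_pool))
  bg <- with_seed(derive_seed(seed, 5000L), {
    sample(background, min(n_bg, length(background)))
  })
  dd_genes_use <- c(dd_gene_pool, sort(bg))
  dd <- dd_test(counts_kept[dd_genes_use, sel, drop = FALSE],
                factor(labels[sel], levels = pair),
                dd_params(), depth_correct = TRUE,
                seed = derive_seed(seed, 6000L))
  write.table(format(dd, digits = 10, trim = TRUE, scientific = NA),
              file.path(out_dir, "dd_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # zero-proportion clustering of the planted/called DD genes
  zp_genes <- dd$gene[dd$category != "none"]
  if (length(zp_genes) < 10L) zp_genes <- dd_genes_use
  zp <- zp_profile(counts_kept, labels, genes = zp_genes,
                   states = sort(unique(labels)))
  km <- kmeans_correlation(zp, k = min(8L, nrow(zp) - 1L),
                           seed = derive_seed(seed, 7000L))
  write_matrix_tsv(zp, file.path(out_dir, "zp_matrix.tsv"), "gene")
  write.table(data.frame(gene = names(km$assignments),
                         cluster = km$assignments),
              file.path(out_dir, "assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(km$centroids_zp, file.path(out_dir, "centroids.tsv"),
                   "cluster")

  # peak-based validation of the final regulons
  domains <- build_domains(sim$annotation)
  assoc <- associate_peaks(sim$peaks, domains)
  val <- lapply(filt$regulons, validate_regulon, associations = assoc)
  val_df <- data.frame(
    regulon = vapply(filt$regulons, regulon_id, character(1)),
    fraction_with_peak = vapply(val, function(v)
      round(v$fraction_with_peak, 6), numeric(1)),
    mean_best_rank = vapply(val, function(v)
      round(v$mean_best_rank, 4), numeric(1)),
    n_targets = vapply(val, function(v) v$n_targets, numeric(1)))
  write.table(val_df, file.path(out_dir, "peak_validation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(sim = sim, discovery = disc, filtered = filt, dd = dd,
                 zp_clusters = km, validation = val, hvgs = hvgs,
                 mad_kept = keep))
}

#' Write regulons as JSON
#'
#' @param regulons List of [regulon()] objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_regulons <- function(regulons, path) {
  payload <- lapply(regulons, function(r) {
    list(tf = r$tf, sign = r$sign, targets = r$targets,
         npred = r$npred, n_iterations_found = r$n_iterations_found)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Fixed-format TSV writer for numeric matrices (deterministic bytes).
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)),
                   format(m, digits = 10, trim = TRUE, scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m) %||%
                   paste0("V", seq_len(ncol(m))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
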