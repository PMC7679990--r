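#' Simulation configuration for ground-truthed single-cell datasets
#'
#' Builds the parameter set for [simulate_counts()] and friends. Defaults
#' emulate a bone-marrow-like differentiation ladder: eight cell states
#' traversed in order (alternating G1 / cycling), planted activating and
#' repressive transcription-factor regulons whose activity is confined to a
#' contiguous block of states, log-normal library sizes, per-donor expression
#' wobble, and mean-dependent dropout that produces state-dependent zero
#' proportions.
#'
#' @param n_states Number of cell states along the trajectory.
#' @param cells_per_state Cells simulated per state.
#' @param n_genes Total genes (includes TFs, mitochondrial and marker genes).
#' @param n_tfs Number of transcription-factor genes; planted regulons use
#'   the first `n_planted_regulons` of them, the rest act as decoys.
#' @param n_planted_regulons Number of regulons with real planted targets.
#' @param targets_per_regulon Targets per planted regulon (disjoint sets).
#' @param regulon_effect log2 fold-change magnitude linking TF activity to
#'   target means in the states where the regulon is active.
#' @param repressive_fraction Fraction of planted regulons with negative sign
#'   (targets go down when the TF is active).
#' @param libsize_mu,libsize_sigma Log-scale mean and SD of per-cell library
#'   sizes (log-normal).
#' @param dropout_midpoint,dropout_slope Logistic dropout curve in log mean:
#'   the per-entry dropout probability is
#'   `plogis(dropout_slope * (dropout_midpoint - log(mu)))`. Setting
#'   `dropout_slope = 0` or `dropout_midpoint = -Inf` disables dropout, so
#'   zeros arise from negative-binomial sampling alone.
#' @param n_donors Number of donors; cells are assigned randomly.
#' @param donor_effect_sd Log-scale SD of per-gene, per-donor multiplicative
#'   effects.
#' @param motif_tpr,motif_fpr True/false positive rates used when building
#'   the motif-annotation table from planted edges.
#' @param peak_tpr,peak_fpr Probabilities of placing a peak near a true
#'   target TSS / a decoy gene TSS.
#' @param dd_de_genes,dd_dm_genes,dd_dz_genes Numbers of genes planted with
#'   a differential-mean, differential-modality, or differential
#'   zero-proportion change between the two pivot states (the middle
#'   consecutive state pair of the trajectory).
#' @param dd_effect log2 effect magnitude for planted DE/DM genes.
#' @param dz_shift Extra dropout probability added to planted DZ genes in
#'   post-pivot states (a zero-proportion shift of roughly this size).
#' @param n_mito_genes Mitochondrial genes (named with the `MT-` prefix).
#' @param n_cycle_genes S-phase markers and G2/M markers (each).
#' @param outlier_frac Fraction of cells planted as QC outliers (half get
#'   8-fold library size, half get 10-fold mitochondrial load).
#' @param nb_dispersion_range Per-gene NB dispersion phi is drawn
#'   log-uniformly from this range; the NB variance is `mu + phi * mu^2`.
#' @param seed Integer seed; all outputs are deterministic given the config.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_states = 8L,
                              cells_per_state = 200L,
                              n_genes = 2000L,
                              n_tfs = 20L,
                              n_planted_regulons = 10L,
                              targets_per_regulon = 30L,
                              regulon_effect = 1.5,
                              repressive_fraction = 0.3,
                              libsize_mu = log(5000),
                              libsize_sigma = 0.25,
                              dropout_midpoint = log(0.25),
                              dropout_slope = 1,
                              n_donors = 4L,
                              donor_effect_sd = 0.1,
                              motif_tpr = 0.9,
                              motif_fpr = 0.01,
                              peak_tpr = 0.8,
                              peak_fpr = 0.05,
                              dd_de_genes = 60L,
                              dd_dm_genes = 20L,
                              dd_dz_genes = 60L,
                              dd_effect = 1.5,
                              dz_shift = 0.4,
                              n_mito_genes = 10L,
                              n_cycle_genes = 20L,
                              outlier_frac = 0.01,
                              nb_dispersion_range = c(0.1, 2),
                              seed = 1L) {
  cfg <- list(
    n_states = as.integer(n_states),
    cells_per_state = as.integer(cells_per_state),
    n_genes = as.integer(n_genes),
    n_tfs = as.integer(n_tfs),
    n_planted_regulons = as.integer(n_planted_regulons),
    targets_per_regulon = as.integer(targets_per_regulon),
    regulon_effect = regulon_effect,
    repressive_fraction = repressive_fraction,
    libsize_mu = libsize_mu,
    libsize_sigma = libsize_sigma,
    dropout_midpoint = dropout_midpoint,
    dropout_slope = dropout_slope,
    n_donors = as.integer(n_donors),
    donor_effect_sd = donor_effect_sd,
    motif_tpr = motif_tpr,
    motif_fpr = motif_fpr,
    peak_tpr = peak_tpr,
    peak_fpr = peak_fpr,
    dd_de_genes = as.integer(dd_de_genes),
    dd_dm_genes = as.integer(dd_dm_genes),
    dd_dz_genes = as.integer(dd_dz_genes),
    dd_effect = dd_effect,
    dz_shift = dz_shift,
    n_mito_genes = as.integer(n_mito_genes),
    n_cycle_genes = as.integer(n_cycle_genes),
    outlier_frac = outlier_frac,
    nb_dispersion_range = nb_dispersion_range,
    seed = as.integer(seed)
  )
  counts <- c("n_states", "cells_per_state", "n_genes", "n_tfs", "n_donors")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop("'", f, "' must be >= 1")
  }
  rates <- c("repressive_fraction", "motif_tpr", "motif_fpr", "peak_tpr",
             "peak_fpr", "outlier_frac", "dz_shift")
  for (f in rates) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must be in [0, 1]")
  }
  if (cfg$regulon_effect < 0) stop("'regulon_effect' must be >= 0")
  if (cfg$n_planted_regulons > cfg$n_tfs) {
    stop("n_planted_regulons must not exceed n_tfs")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a ground-truthed UMI count matrix
#'
#' Draws per-cell UMI counts from a negative-binomial model in which each
#' gene's per-cell mean is `baseline(state) x regulon multiplier x donor
#' factor`, rescaled so the cell's expected total equals its log-normal
#' library size, followed by mean-dependent Bernoulli dropout. Target genes
#' of a planted regulon respond to the TF's latent (state-level) activity:
#' in states where the regulon is active, the TF's own mean is raised
#' `2^regulon_effect`-fold and each target's mean is multiplied by
#' `2^(+-regulon_effect)` according to the regulon sign.
#'
#' Beyond regulons, the generator plants: genes with differential mean (DE),
#' modality (DM; a per-cell half/half mixture of up- and down-shifted means)
#' or zero proportion (DZ; extra dropout) between the two middle states of
#' the trajectory; S and G2/M marker genes elevated in cycling states; and a
#' small set of QC outlier cells (inflated library size or mitochondrial
#' load).
#'
#' @param config A [simulation_config()].
#' @param keep_latent Also return the latent per-cell NB means (`mu`) and
#'   per-gene dispersions (`phi`) in the truth, for oracle checks of the
#'   sampling distribution. Off by default (they are large).
#' @return A list with elements:
#'   \describe{
#'     \item{sce}{A [SingleCellExperiment::SingleCellExperiment] with a
#'       sparse `counts` assay (genes x cells) and per-cell metadata
#'       (`donor`, `state`, `phase`, `total_umi`, `mito_frac`).}
#'     \item{truth}{All planted structure: `planted_regulons` (list of
#'       [regulon()] objects), `dd_genes` (gene, true category, the state
#'       pair it applies to), `state_labels`, `outlier_cells`, `s_genes`,
#'       `g2m_genes`, `tf_genes`, and the config.}
#'   }
#' @export
simulate_counts <- function(config, keep_latent = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  n_special <- cfg$n_mito_genes + cfg$n_tfs + 2L * cfg$n_cycle_genes +
    cfg$n_planted_regulons * cfg$targets_per_regulon +
    cfg$dd_de_genes + cfg$dd_dm_genes + cfg$dd_dz_genes
  if (n_special > cfg$n_genes) stop("insufficient genes")

  with_seed(derive_seed(cfg$seed, 1L), {
    n_cells <- cfg$n_states * cfg$cells_per_state
    states <- paste0("state", seq_len(cfg$n_states))
    state_of_cell <- rep(states, each = cfg$cells_per_state)
    cycling_state <- rep(c(FALSE, TRUE), length.out = cfg$n_states)
    names(cycling_state) <- states

    # gene roles: mito, TFs, cycle markers, regulon targets, DD-planted, rest
    gene_names <- sprintf("G%05d", seq_len(cfg$n_genes))
    mito_idx <- seq_len(cfg$n_mito_genes)
    gene_names[mito_idx] <- paste0("MT-", seq_len(cfg$n_mito_genes))
    tf_idx <- cfg$n_mito_genes + seq_len(cfg$n_tfs)
    gene_names[tf_idx] <- paste0("TF", seq_len(cfg$n_tfs))
    nxt <- cfg$n_mito_genes + cfg$n_tfs
    s_idx <- nxt + seq_len(cfg$n_cycle_genes); nxt <- nxt + cfg$n_cycle_genes
    g2m_idx <- nxt + seq_len(cfg$n_cycle_genes); nxt <- nxt + cfg$n_cycle_genes
    target_idx <- matrix(
      nxt + seq_len(cfg$n_planted_regulons * cfg$targets_per_regulon),
      nrow = cfg$targets_per_regulon)
    nxt <- nxt + length(target_idx)
    de_idx <- nxt + seq_len(cfg$dd_de_genes); nxt <- nxt + cfg$dd_de_genes
    dm_idx <- nxt + seq_len(cfg$dd_dm_genes); nxt <- nxt + cfg$dd_dm_genes
    dz_idx <- nxt + seq_len(cfg$dd_dz_genes); nxt <- nxt + cfg$dd_dz_genes

    # planted regulons: contiguous active-state blocks along the trajectory
    n_rep <- round(cfg$repressive_fraction * cfg$n_planted_regulons)
    signs <- c(rep("-", n_rep),
               rep("+", cfg$n_planted_regulons - n_rep))
    signs <- sample(signs)
    block_len <- max(2L, round(cfg$n_states / 3))
    block_len <- min(block_len, cfg$n_states)
    active_states <- lapply(seq_len(cfg$n_planted_regulons), function(r) {
      start <- sample.int(cfg$n_states - block_len + 1L, 1L)
      states[start:(start + block_len - 1L)]
    })

    # baseline relative rates; TFs and DE/DM plants kept well-expressed so
    # their nonzero distributions carry signal, mito genes sized for a ~2%
    # mitochondrial fraction. Repressed targets need a high baseline for
    # their down-regulation to be observable above the dropout floor.
    base <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1.25)
    base[tf_idx] <- rlnorm(cfg$n_tfs, meanlog = 2, sdlog = 0.3)
    base[target_idx] <- rlnorm(length(target_idx), meanlog = 1, sdlog = 0.5)
    rep_targets <- target_idx[, signs == "-", drop = FALSE]
    base[rep_targets] <- rlnorm(length(rep_targets), meanlog = 1.7,
                                sdlog = 0.4)
    base[de_idx] <- rlnorm(cfg$dd_de_genes, meanlog = 1.5, sdlog = 0.3)
    base[dm_idx] <- rlnorm(cfg$dd_dm_genes, meanlog = 1.5, sdlog = 0.3)
    base[dz_idx] <- rlnorm(cfg$dd_dz_genes, meanlog = 0.5, sdlog = 0.3)
    base[mito_idx] <- sum(base) * 0.02 / cfg$n_mito_genes

    # per-gene per-state multipliers
    state_mult <- matrix(1, cfg$n_genes, cfg$n_states,
                         dimnames = list(gene_names, states))
    for (r in seq_len(cfg$n_planted_regulons)) {
      act <- states %in% active_states[[r]]
      state_mult[tf_idx[r], act] <- 2^cfg$regulon_effect
      eff <- if (signs[r] == "+") cfg$regulon_effect else -cfg$regulon_effect
      state_mult[target_idx[, r], act] <- 2^eff
    }
    pivot <- max(1L, cfg$n_states %/% 2L)
    post_pivot <- seq_len(cfg$n_states) > pivot
    # DE plants: half up, half down after the pivot state
    de_dir <- rep(c(1, -1), length.out = cfg$dd_de_genes)
    state_mult[de_idx, post_pivot] <-
      state_mult[de_idx, post_pivot] * 2^(de_dir * cfg$dd_effect)
    # cycle markers elevated in cycling states (refined per cell below)
    state_mult[c(s_idx, g2m_idx), cycling_state] <- 2^1.5

    # donors and library sizes
    donor <- sample(paste0("donor", seq_len(cfg$n_donors)), n_cells,
                    replace = TRUE)
    donor_fac <- matrix(
      exp(rnorm(cfg$n_genes * cfg$n_donors, sd = cfg$donor_effect_sd)),
      cfg$n_genes, cfg$n_donors,
      dimnames = list(gene_names, paste0("donor", seq_len(cfg$n_donors))))
    libsize <- rlnorm(n_cells, meanlog = cfg$libsize_mu,
                      sdlog = cfg$libsize_sigma)

    # planted QC outliers: half huge libraries, half high mito load
    n_out <- round(cfg$outlier_frac * n_cells)
    outlier_cells <- sort(sample.int(n_cells, n_out))
    out_lib <- outlier_cells[seq_len(n_out %/% 2)]
    out_mito <- setdiff(outlier_cells, out_lib)
    libsize[out_lib] <- libsize[out_lib] * 8

    # per-cell phase within cycling states
    phase <- rep("G1", n_cells)
    cyc_cells <- which(cycling_state[state_of_cell])
    phase[cyc_cells] <- sample(c("S", "G2M"), length(cyc_cells),
                               replace = TRUE)

    # assemble the rate matrix genes x cells
    rate <- state_mult[, state_of_cell, drop = FALSE] *
      donor_fac[, donor, drop = FALSE]
    # DM plants: per-cell bimodal mixture after the pivot
    dm_cells <- which(post_pivot[match(state_of_cell, states)])
    if (length(dm_idx) > 0 && length(dm_cells) > 0) {
      flips <- matrix(sample(c(1, -1),
                             length(dm_idx) * length(dm_cells),
                             replace = TRUE),
                      length(dm_idx), length(dm_cells))
      rate[dm_idx, dm_cells] <- rate[dm_idx, dm_cells] *
        2^(flips * cfg$dd_effect)
    }
    # phase-specific marker boost (on top of the state-level elevation)
    rate[s_idx, phase == "S"] <- rate[s_idx, phase == "S"] * 2
    rate[g2m_idx, phase == "G2M"] <- rate[g2m_idx, phase == "G2M"] * 2
    rate[mito_idx, out_mito] <- rate[mito_idx, out_mito] * 10
    rate <- rate * base

    mu <- sweep(rate, 2, libsize / colSums(rate), "*")

    phi <- exp(runif(cfg$n_genes, log(cfg$nb_dispersion_range[1]),
                     log(cfg$nb_dispersion_range[2])))
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = rep(1 / phi, n_cells)),
      cfg$n_genes, n_cells)

    # mean-dependent dropout (disabled when slope 0 or midpoint -Inf)
    if (cfg$dropout_slope != 0 && is.finite(cfg$dropout_midpoint)) {
      pdrop <- stats::plogis(
        cfg$dropout_slope * (cfg$dropout_midpoint - log(mu)))
      counts[runif(length(mu)) < pdrop] <- 0L
    }
    # DZ plants: extra dropout after the pivot
    if (length(dz_idx) > 0 && cfg$dz_shift > 0) {
      dzc <- which(post_pivot[match(state_of_cell, states)])
      drop <- matrix(runif(length(dz_idx) * length(dzc)) < cfg$dz_shift,
                     length(dz_idx), length(dzc))
      block <- counts[dz_idx, dzc, drop = FALSE]
      block[drop] <- 0L
      counts[dz_idx, dzc] <- block
    }

    dimnames(counts) <- list(gene_names, sprintf("cell%05d",
                                                 seq_len(n_cells)))
    total_umi <- colSums(counts)
    mito_frac <- colSums(counts[mito_idx, , drop = FALSE]) /
      pmax(total_umi, 1)

    regs <- lapply(seq_len(cfg$n_planted_regulons), function(r) {
      regulon(tf = gene_names[tf_idx[r]], sign = signs[r],
              targets = gene_names[target_idx[, r]],
              active_states = active_states[[r]])
    })
    n_dd <- length(de_idx) + length(dm_idx) + length(dz_idx)
    dd_genes <- data.frame(
      gene = gene_names[c(de_idx, dm_idx, dz_idx)],
      category = rep(c("DE", "DM", "DZ"),
                     c(length(de_idx), length(dm_idx), length(dz_idx))),
      state_a = rep(states[pivot], n_dd),
      state_b = rep(states[pivot + 1L], n_dd),
      stringsAsFactors = FALSE)

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(Matrix::Matrix(counts,
                                                        sparse = TRUE),
                                         "CsparseMatrix")),
      colData = S4Vectors::DataFrame(
        donor = donor, state = state_of_cell, phase = phase,
        total_umi = total_umi, mito_frac = mito_frac,
        row.names = colnames(counts)),
      rowData = S4Vectors::DataFrame(
        is_tf = seq_len(cfg$n_genes) %in% tf_idx,
        is_mito = seq_len(cfg$n_genes) %in% mito_idx,
        row.names = gene_names))

    truth <- list(
      planted_regulons = regs,
      dd_genes = dd_genes,
      state_labels = stats::setNames(state_of_cell, colnames(counts)),
      outlier_cells = colnames(counts)[outlier_cells],
      s_genes = gene_names[s_idx],
      g2m_genes = gene_names[g2m_idx],
      tf_genes = gene_names[tf_idx],
      gene_universe = gene_names,
      cycling_states = states[cycling_state],
      config = cfg)
    if (keep_latent) {
      truth$mu <- mu
      truth$phi <- phi
    }
    S4Vectors::metadata(sce)$truth <- truth
    list(sce = sce, truth = truth)
  })
}

#' Negative-binomial zero mass
#'
#' Closed-form probability of a zero count under NB(mu, phi) with variance
#' `mu + phi mu^2`: `(1 + mu * phi)^(-1/phi)`. Used as an oracle for the
#' simulator's zero proportions when dropout is disabled.
#'
#' @param mu NB mean (scalar, vector or matrix).
#' @param phi NB dispersion (recycled against `mu`).
#' @return Zero probability.
#' @export
nb_zero_mass <- function(mu, phi) (1 + mu * phi)^(-1 / phi)

#' Build a motif-annotation table from planted truth
#'
#' Each true TF-target edge enters the table with probability `motif_tpr`;
#' every other (TF, gene) pair with probability `motif_fpr`. Stands in for
#' the motif-based pruning evidence used by regulon discovery.
#'
#' @param truth Truth list from [simulate_counts()].
#' @param config The same [simulation_config()].
#' @return A data.frame with columns `tf`, `gene`.
#' @export
simulate_motif_table <- function(truth, config) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, 2L), {
    tfs <- truth$tf_genes
    all_genes <- truth$gene_universe
    if (is.null(all_genes)) stop("truth must carry 'gene_universe'")
    true_edges <- do.call(rbind, lapply(truth$planted_regulons, function(r) {
      data.frame(tf = r$tf, gene = r$targets, stringsAsFactors = FALSE)
    }))
    if (is.null(true_edges)) {
      true_edges <- data.frame(tf = character(), gene = character())
    }
    keep_true <- runif(nrow(true_edges)) < cfg$motif_tpr
    true_kept <- true_edges[keep_true, , drop = FALSE]
    true_key <- paste(true_edges$tf, true_edges$gene)

    rows <- vector("list", length(tfs))
    for (i in seq_along(tfs)) {
      cand <- setdiff(all_genes, tfs[i])
      cand <- cand[!(paste(tfs[i], cand) %in% true_key)]
      hit <- cand[runif(length(cand)) < cfg$motif_fpr]
      rows[[i]] <- data.frame(tf = rep(tfs[i], length(hit)), gene = hit,
                              stringsAsFactors = FALSE)
    }
    out <- rbind(true_kept, do.call(rbind, rows))
    rownames(out) <- NULL
    out[order(out$tf, out$gene), , drop = FALSE]
  })
}

#' Gene annotation on a synthetic chromosome
#'
#' Places genes on a single chromosome `chrS` on a regular grid with
#' alternating strands; enough to exercise all interval logic without real
#' genome coordinates.
#'
#' @param genes Character vector of gene names.
#' @param spacing Distance between successive TSSs (bp).
#' @param offset Position of the first TSS (bp).
#' @return data.frame with `gene`, `chrom`, `tss`, `strand`, and the
#'   declared `chrom_length` as an attribute.
#' @export
synthetic_gene_annotation <- function(genes, spacing = 50000L,
                                      offset = 100000L) {
  n <- length(genes)
  ann <- data.frame(
    gene = genes,
    chrom = "chrS",
    tss = offset + (seq_len(n) - 1L) * spacing,
    strand = rep(c("+", "-"), length.out = n),
    stringsAsFactors = FALSE)
  attr(ann, "chrom_length") <- offset + n * spacing + offset
  ann
}

#' Simulate ChIP-seq-like peaks concordant with planted regulon targets
#'
#' For every true planted target, with probability `peak_tpr` a peak of
#' width 200-600 bp is centered uniformly within +-2 kb of its TSS; decoy
#' peaks appear near non-target genes with probability `peak_fpr`. Scores
#' decrease in placement order, and ranks follow scores (rank 1 = best).
#'
#' @param truth Truth list from [simulate_counts()].
#' @param gene_annotation Annotation from [synthetic_gene_annotation()].
#' @param config The same [simulation_config()].
#' @return A `peak_set` data.frame (see [read_peaks()]).
#' @export
simulate_peaks <- function(truth, gene_annotation, config) {
  cfg <- config
  chrom_len <- attr(gene_annotation, "chrom_length") %||% Inf
  if (any(gene_annotation$tss < 0 | gene_annotation$tss > chrom_len)) {
    stop("TSS outside declared chromosome length")
  }
  with_seed(derive_seed(cfg$seed, 3L), {
    targets <- unique(unlist(lapply(truth$planted_regulons,
                                    function(r) r$targets)))
    is_target <- gene_annotation$gene %in% targets
    p_hit <- ifelse(is_target, cfg$peak_tpr, cfg$peak_fpr)
    n <- nrow(gene_annotation)
    # all randomness drawn up-front: under a fixed seed, raising tpr/fpr
    # yields a superset of peaks (monotone ladder)
    u_hit <- runif(n)
    offset <- runif(n, -2000, 2000)
    width <- round(runif(n, 200, 600))
    # place true-target peaks first so they receive the best scores
    ord <- order(!is_target, seq_len(n))
    rows <- list()
    for (i in ord) {
      if (u_hit[i] >= p_hit[i]) next
      mid <- round(gene_annotation$tss[i] + offset[i])
      start <- max(0L, mid - width[i] %/% 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = gene_annotation$chrom[i], start = start,
        end = start + width[i],
        name = paste0("peak_", gene_annotation$gene[i]),
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) {
      return(empty_peak_set())
    }
    out <- do.call(rbind, rows)
    out$score <- round(seq(1000, 10, length.out = nrow(out)), 3)
    out$strand <- "."
    out$rank <- seq_len(nrow(out))
    as_peak_set(out)
  })
}

#' Simulate a complete dataset: counts, truth, motif table, annotation, peaks
#'
#' Convenience wrapper running [simulate_counts()],
#' [simulate_motif_table()], [synthetic_gene_annotation()] and
#' [simulate_peaks()] under one config.
#'
#' @param config A [simulation_config()].
#' @return List with `sce`, `truth`, `motifs`, `annotation`, `peaks`.
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_counts(config)
  sim$truth$gene_universe <- rownames(sim$sce)
  motifs <- simulate_motif_table(sim$truth, config)
  ann <- synthetic_gene_annotation(rownames(sim$sce))
  peaks <- simulate_peaks(sim$truth, ann, config)
  list(sce = sim$sce, truth = sim$truth, motifs = motifs,
       annotation = ann, peaks = peaks)
}
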