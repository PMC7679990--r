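#' Peak sets
#'
#' A `peak_set` is a data.frame with columns `chrom`, `start`, `end`
#' (0-based half-open), `name`, `score`, `strand` and `rank` (1 = best
#' score). Constructed by [read_peaks()], [simulate_peaks()] or
#' [as_peak_set()].
#'
#' @param df data.frame with at least `chrom`, `start`, `end`, `score`.
#' @return A ranked `peak_set`.
#' @export
as_peak_set <- function(df) {
  need <- c("chrom", "start", "end", "score")
  if (!all(need %in% names(df))) {
    stop("peak set needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) > 0 && any(df$start >= df$end)) {
    stop("all peaks must satisfy start < end")
  }
  if (is.null(df$name)) df$name <- paste0("peak", seq_len(nrow(df)))
  if (is.null(df$strand)) df$strand <- "."
  # rank 1 = best score; ties broken by genomic position
  ord <- order(-df$score, df$chrom, df$start)
  df$rank <- integer(nrow(df))
  df$rank[ord] <- seq_len(nrow(df))
  rownames(df) <- NULL
  df <- df[, c("chrom", "start", "end", "name", "score", "strand", "rank")]
  class(df) <- c("peak_set", "data.frame")
  df
}

empty_peak_set <- function() {
  as_peak_set(data.frame(chrom = character(), start = integer(),
                         end = integer(), name = character(),
                         score = numeric(), strand = character(),
                         stringsAsFactors = FALSE))
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' Read peaks from BED or narrowPeak files
#'
#' Intervals are interpreted as 0-based half-open. The score comes from
#' column 5 for BED and column 7 (signalValue) for narrowPeak; override
#' with `score_col`. Malformed lines are reported with their line number.
#'
#' @param path File path.
#' @param format `"BED"` or `"narrowPeak"`.
#' @param score_col Optional 1-based column index for the score.
#' @return A `peak_set`.
#' @export
read_peaks <- function(path, format = c("BED", "narrowPeak"),
                       score_col = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L || all(lines == "")) return(empty_peak_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- if (format == "BED") 3L else 10L
  nf <- lengths(fields)
  bad <- which(nf < min_cols)
  if (length(bad) > 0L) {
    stop("malformed ", format, " line ", bad[1], ": expected >= ",
         min_cols, " fields, got ", nf[bad[1]])
  }
  get_col <- function(i, default = NA) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else
      as.character(default), character(1))
  }
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("malformed ", format, " line ", bad,
         ": non-integer start/end")
  }
  score_col <- score_col %||% if (format == "BED") 5L else 7L
  score <- suppressWarnings(as.numeric(get_col(score_col, 0)))
  score[is.na(score)] <- 0
  as_peak_set(data.frame(
    chrom = get_col(1), start = start, end = end,
    name = get_col(4, "."), score = score,
    strand = get_col(6, "."), stringsAsFactors = FALSE))
}

#' Write a peak set as BED6
#'
#' @param peaks A `peak_set`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_peaks <- function(peaks, path) {
  df <- peaks[, c("chrom", "start", "end", "name", "score", "strand")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Pool and merge peak sets from replicates
#'
#' Unions the intervals of all inputs and merges overlapping or bookended
#' intervals; a merged peak's score is the maximum over its members.
#'
#' @param peaksets List of `peak_set` objects (or a single one).
#' @return A merged `peak_set`.
#' @export
pool_merge_peaks <- function(peaksets) {
  if (is.data.frame(peaksets)) peaksets <- list(peaksets)
  pooled <- do.call(rbind, lapply(peaksets, function(p) {
    as.data.frame(p)[, c("chrom", "start", "end", "score")]
  }))
  if (nrow(pooled) == 0L) return(empty_peak_set())
  gr <- GenomicRanges::GRanges(
    seqnames = pooled$chrom,
    ranges = IRanges::IRanges(start = pooled$start + 1L, end = pooled$end),
    score = pooled$score)
  merged <- GenomicRanges::reduce(gr) # merges overlapping + bookended
  hits <- GenomicRanges::findOverlaps(merged, gr)
  max_score <- vapply(split(gr$score[S4Vectors::subjectHits(hits)],
                            S4Vectors::queryHits(hits)), max, numeric(1))
  as_peak_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    score = as.numeric(max_score), stringsAsFactors = FALSE))
}

#' Keep the top-n peaks by score
#'
#' Ties are broken by genomic position (chrom, then start). The result is
#' re-ranked 1..n.
#'
#' @param peaks A `peak_set`.
#' @param n Number of peaks to keep (default 10,000).
#' @return A `peak_set` with at most `n` rows.
#' @export
select_top_peaks <- function(peaks, n = 10000L) {
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  kept <- peaks[ord[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
  as_peak_set(as.data.frame(kept))
}

#' Discard peaks overlapping annotated TSSs
#'
#' Removes peaks overlapping `[tss - w, tss + w)` for any gene; with the
#' default `w = 0` a peak is removed only when it covers the TSS base
#' itself.
#'
#' @param peaks A `peak_set`.
#' @param annotation Gene annotation with `chrom`, `tss` columns.
#' @param tss_window Half-width `w` in bp.
#' @return The filtered `peak_set`.
#' @export
filter_tss_overlap <- function(peaks, annotation, tss_window = 0L) {
  if (nrow(peaks) == 0L) return(peaks)
  # half-open [tss - w, tss + w); w = 0 degenerates to the TSS base itself
  tss_gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(
      start = annotation$tss - tss_window + 1L,
      end = pmax(annotation$tss + tss_window, annotation$tss + 1L)))
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(peaks), tss_gr)
  drop <- unique(S4Vectors::queryHits(hits))
  out <- as.data.frame(peaks)
  if (length(drop) > 0L) out <- out[-drop, , drop = FALSE]
  as_peak_set(out)
}

#' Build basal-plus-extension regulatory domains
#'
#' Each gene's basal domain spans `basal_up` bp upstream to `basal_down`
#' bp downstream of its TSS in gene orientation (`[tss - 5000, tss +
#' 1000)` on `+`, mirrored on `-`). Each basal edge then extends outward
#' to the nearest neighboring gene's basal-domain edge or by `max_ext`,
#' whichever is closer; extensions never invade a neighbor's basal
#' region. Coordinates are clipped at zero.
#'
#' @param annotation data.frame with `gene`, `chrom`, `tss`, `strand`.
#' @param basal_up,basal_down Basal extents (bp) up/downstream of the TSS.
#' @param max_ext Maximum extension (bp) beyond the basal edge.
#' @return The annotation with `basal_start`, `basal_end`, `dom_start`,
#'   `dom_end` columns (0-based half-open).
#' @export
build_domains <- function(annotation, basal_up = 5000L, basal_down = 1000L,
                          max_ext = 1000000L) {
  ann <- as.data.frame(annotation)
  if (anyDuplicated(ann$gene)) stop("duplicate gene ids in annotation")
  plus <- ann$strand == "+"
  ann$basal_start <- ifelse(plus, ann$tss - basal_up, ann$tss - basal_down)
  ann$basal_end <- ifelse(plus, ann$tss + basal_down, ann$tss + basal_up)
  ann$basal_start <- pmax(0L, ann$basal_start)

  ann$dom_start <- pmax(0, ann$basal_start - max_ext)
  ann$dom_end <- ann$basal_end + max_ext
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    ord <- idx[order(ann$basal_start[idx], ann$basal_end[idx])]
    bs <- ann$basal_start[ord]
    be <- ann$basal_end[ord]
    n <- length(ord)
    # nearest basal edge upstream: running max of preceding basal ends;
    # a value above this gene's basal start means an overlapping neighbor
    # blocks any upstream extension (clamped to the basal edge)
    prev_max_end <- c(-Inf, cummax(be)[-n])
    up_limit <- pmin(prev_max_end, bs)
    # genes are sorted by basal start, so the next gene's basal start is
    # the nearest downstream basal edge; clamp blocks extension when the
    # neighbor's basal already overlaps
    next_start <- c(bs[-1], Inf)
    down_limit <- pmax(next_start, be)
    ann$dom_start[ord] <- pmax(ann$dom_start[ord], up_limit)
    ann$dom_end[ord] <- pmin(ann$dom_end[ord], down_limit)
    ann$dom_start[ord] <- pmax(0, ann$dom_start[ord])
  }
  ann$dom_start <- as.numeric(ann$dom_start)
  ann$dom_end <- as.numeric(ann$dom_end)
  ann
}

#' Associate peaks with genes through regulatory domains
#'
#' A peak is assigned to every gene whose regulatory domain contains the
#' peak's midpoint (`floor((start + end) / 2)`); a peak in the overlap of
#' two domains yields two associations. Per gene, the number of peaks,
#' their ranks and their signed distances from peak midpoint to TSS
#' (positive downstream of the TSS in gene orientation) are recorded.
#' With `use_midpoint = FALSE` any interval overlap with the domain
#' associates instead.
#'
#' @param peaks A `peak_set`.
#' @param domains Annotation with domains from [build_domains()].
#' @param use_midpoint Midpoint rule (default) or whole-interval overlap.
#' @return data.frame with one row per gene: `gene`, `n_peaks`,
#'   `peak_ranks` (list column), `distances` (list column).
#' @export
associate_peaks <- function(peaks, domains, use_midpoint = TRUE) {
  dom_gr <- GenomicRanges::GRanges(
    seqnames = domains$chrom,
    ranges = IRanges::IRanges(start = domains$dom_start + 1L,
                              end = domains$dom_end))
  mid <- floor((peaks$start + peaks$end) / 2)
  peak_gr <- if (use_midpoint) {
    GenomicRanges::GRanges(seqnames = peaks$chrom,
                           ranges = IRanges::IRanges(start = mid + 1L,
                                                     width = 1L))
  } else {
    peaks_to_granges(peaks)
  }
  hits <- GenomicRanges::findOverlaps(peak_gr, dom_gr)
  pk <- S4Vectors::queryHits(hits)
  gn <- S4Vectors::subjectHits(hits)
  dist <- mid[pk] - domains$tss[gn]
  dist[domains$strand[gn] == "-"] <- -dist[domains$strand[gn] == "-"]

  res <- lapply(seq_len(nrow(domains)), function(g) {
    sel <- gn == g
    data.frame(gene = domains$gene[g], n_peaks = sum(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$peak_ranks <- lapply(seq_len(nrow(domains)), function(g) {
    peaks$rank[pk[gn == g]]
  })
  out$distances <- lapply(seq_len(nrow(domains)), function(g) {
    dist[gn == g]
  })
  rownames(out) <- NULL
  out
}

#' Validate a regulon's targets against peak evidence
#'
#' Reports the fraction of predicted targets with at least one associated
#' peak, the same fraction stratified by `Npred` (the number of discovery
#' iterations supporting each target), and the mean best (lowest) peak
#' rank among targets with peaks. Targets absent from the annotation
#' count in the denominator and are reported.
#'
#' @param reg A [regulon()].
#' @param associations Output of [associate_peaks()].
#' @return List with `fraction_with_peak`, `by_npred` (data.frame),
#'   `mean_best_rank`, `n_targets`, `missing_from_annotation`.
#' @export
validate_regulon <- function(reg, associations) {
  if (!inherits(reg, "regulon") || length(reg$targets) == 0L) {
    stop("a non-empty regulon is required")
  }
  idx <- match(reg$targets, associations$gene)
  n_peaks <- ifelse(is.na(idx), 0L, associations$n_peaks[idx])
  has_peak <- n_peaks > 0
  best_rank <- vapply(seq_along(idx), function(i) {
    if (is.na(idx[i]) || n_peaks[i] == 0L) return(NA_real_)
    min(associations$peak_ranks[[idx[i]]])
  }, numeric(1))
  npred <- reg$npred
  by_npred <- do.call(rbind, lapply(sort(unique(npred)), function(np) {
    sel <- npred == np
    data.frame(npred = np, n_targets = sum(sel),
               fraction_with_peak = mean(has_peak[sel]),
               mean_n_peaks = mean(n_peaks[sel]))
  }))
  rownames(by_npred) <- NULL
  list(fraction_with_peak = mean(has_peak),
       by_npred = by_npred,
       mean_best_rank = if (any(has_peak)) {
         mean(best_rank[has_peak])
       } else NA_real_,
       n_targets = length(reg$targets),
       missing_from_annotation = reg$targets[is.na(idx)])
}
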