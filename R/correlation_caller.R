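# The open-chromatin pairwise-correlation caller: correlate normalized,
# logged accessibility of consensus peaks across cell types, then anchor
# highly correlated, nearby peak pairs at gene TSSs.

#' Configuration for the correlation caller
#'
#' @param max_pair_distance only peak pairs closer than this are tested
#'   (default 500 kb).
#' @param r_threshold calls require a Pearson correlation strictly above this
#'   (default 0.7).
#' @param pseudocount added to normalized counts before log10 (default 1).
#' @return a list of class `correlation_call_config`.
#' @export
correlation_call_config <- function(max_pair_distance = 5e5,
                                    r_threshold = 0.7, pseudocount = 1) {
  if (max_pair_distance <= 0) stop("max_pair_distance must be positive")
  if (r_threshold < -1 || r_threshold > 1)
    stop("r_threshold must lie in [-1, 1]")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  structure(list(max_pair_distance = max_pair_distance,
                 r_threshold = r_threshold, pseudocount = pseudocount),
            class = "correlation_call_config")
}

#' Build consensus peaks from per-cell-type peak sets
#'
#' Concatenates, sorts and merges the peak sets and assigns each consensus
#' peak a deterministic `chrom:start-end` id.
#'
#' @param peak_sets list of interval data.frames, one per cell type.
#' @return merged interval data.frame with ids.
#' @export
consensus_peaks <- function(peak_sets) {
  merged <- merge_intervals(do.call(rbind, lapply(peak_sets, function(p)
    validate_intervals(p)[, c("chrom", "start", "end", "id", "strand")])))
  merged$id <- sprintf("%s:%d-%d", merged$chrom, as.integer(merged$start),
                       as.integer(merged$end))
  merged
}

# gap between two disjoint half-open intervals on one chromosome, measured
# between nearest covered bases (0 when they overlap) — the same convention
# as min_tss_distance.
.interval_gap <- function(s1, e1, s2, e2) {
  if (s1 > s2) { tmp <- s1; s1 <- s2; s2 <- tmp; tmp <- e1; e1 <- e2; e2 <- tmp }
  if (s2 < e1) 0 else s2 - (e1 - 1)
}

#' Call E/G links from pairwise accessibility correlation
#'
#' Reproduces the open-chromatin correlation pipeline: merge per-cell-type
#' peaks into consensus peaks; normalize each cell type's per-peak counts by
#' that cell type's total mapped reads in peaks; take log10 with a
#' pseudocount; compute the Pearson correlation of every same-chromosome
#' peak pair closer than `max_pair_distance`; keep pairs with correlation
#' strictly above `r_threshold` for which one of the two peaks overlaps a
#' gene TSS — the call is then (other peak, that gene). When both peaks of a
#' pair sit on TSSs, each anchors a call for the other.
#'
#' @param peaks either a list of per-cell-type interval data.frames (merged
#'   internally via [consensus_peaks()]) or an already-consensus interval
#'   data.frame with unique ids.
#' @param counts numeric matrix of raw read counts, consensus peaks x cell
#'   types; rows are matched to peaks by rowname when present, otherwise by
#'   order.
#' @param genes gene annotation (`gene_id`, `chrom`, `tss`).
#' @param config a [correlation_call_config()].
#' @return data.frame with `element_id`, `gene_id`, `tss_peak_id`,
#'   `correlation`, `distance`; one row per distinct call.
#' @export
call_correlation_pairs <- function(peaks, counts, genes,
                                   config = correlation_call_config()) {
  stopifnot(inherits(config, "correlation_call_config"))
  if (is.data.frame(peaks)) {
    peaks <- validate_intervals(peaks, "consensus peaks")
    if (any(is.na(peaks$id)) || anyDuplicated(peaks$id))
      stop("consensus peaks need unique ids")
  } else {
    peaks <- consensus_peaks(peaks)
  }
  .check_gene_annotation(genes)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 cell types")
  if (!is.null(rownames(counts))) {
    miss <- setdiff(peaks$id, rownames(counts))
    if (length(miss) > 0)
      stop("counts lack consensus peak row(s): ", paste(miss, collapse = ", "))
    counts <- counts[peaks$id, , drop = FALSE]
  } else if (nrow(counts) != nrow(peaks)) {
    stop("counts rows must cover all consensus peaks")
  }
  totals <- colSums(counts)
  if (any(totals == 0)) stop("cell type with zero mapped reads in peaks")
  lognorm <- log10(sweep(counts, 2, totals, "/") + config$pseudocount)

  # genes whose TSS each peak covers
  tss_hit <- lapply(seq_len(nrow(peaks)), function(i) {
    on <- genes$chrom == peaks$chrom[i] & genes$tss >= peaks$start[i] &
      genes$tss < peaks$end[i]
    unique(genes$gene_id[on])
  })

  calls <- list()
  n <- nrow(peaks)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (peaks$chrom[i] != peaks$chrom[j]) next
      gap <- .interval_gap(peaks$start[i], peaks$end[i],
                           peaks$start[j], peaks$end[j])
      if (gap >= config$max_pair_distance) next
      if (stats::sd(lognorm[i, ]) == 0 || stats::sd(lognorm[j, ]) == 0) next
      r <- stats::cor(lognorm[i, ], lognorm[j, ])
      if (!(r > config$r_threshold)) next
      for (g in tss_hit[[i]])
        calls[[length(calls) + 1]] <- data.frame(
          element_id = peaks$id[j], gene_id = g, tss_peak_id = peaks$id[i],
          correlation = r, distance = gap, stringsAsFactors = FALSE)
      for (g in tss_hit[[j]])
        calls[[length(calls) + 1]] <- data.frame(
          element_id = peaks$id[i], gene_id = g, tss_peak_id = peaks$id[j],
          correlation = r, distance = gap, stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0)
    return(data.frame(element_id = character(0), gene_id = character(0),
                      tss_peak_id = character(0), correlation = numeric(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[!duplicated(out[, c("element_id", "gene_id", "tss_peak_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
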