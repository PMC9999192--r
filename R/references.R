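# Construction of labeled ground-truth reference sets: distance-matched
# negatives (BENGI rule), genetic-screen filtering (CRiFF rules) and
# prediction whitelists.

#' Distance-matched negatives for a positive reference set
#'
#' For each enhancer of the positive set, every annotated gene that is not
#' its positive partner and lies within the 95th percentile of the positive
#' pairs' element-TSS distances becomes a label-0 pair. The percentile is
#' computed over the positive set itself (linear interpolation between order
#' statistics, quantile type 7) and is recorded in the result's attributes.
#'
#' @param positives data.frame of label-1 pairs (`element_id`, `gene_id`).
#' @param elements interval table locating every positive element by id.
#' @param genes gene annotation (`gene_id`, `chrom`, `tss`); defines the gene
#'   universe negatives are drawn from.
#' @param percentile distance percentile defining the cutoff (default 0.95).
#' @return data.frame of label-0 pairs, disjoint from `positives`, with
#'   attributes `distance_cutoff` and `percentile`.
#' @export
make_bengi_negatives <- function(positives, elements, genes,
                                 percentile = 0.95) {
  if (nrow(positives) == 0) stop("positive set is empty")
  pos <- .join_elements(positives[, c("element_id", "gene_id")], elements)
  d_pos <- .pair_tss_distances(pos, genes)
  if (any(!is.finite(d_pos)))
    stop("positive pair on different chromosomes: ",
         pos$element_id[!is.finite(d_pos)][1])
  cutoff <- unname(stats::quantile(d_pos, percentile, type = 7))

  pos_key <- paste(positives$element_id, positives$gene_id, sep = "\r")
  gene_ids <- unique(genes$gene_id)
  enh <- unique(positives$element_id)
  cand <- data.frame(element_id = rep(enh, each = length(gene_ids)),
                     gene_id = rep(gene_ids, times = length(enh)),
                     stringsAsFactors = FALSE)
  cand <- cand[!(paste(cand$element_id, cand$gene_id, sep = "\r") %in% pos_key), ,
               drop = FALSE]
  cand <- .join_elements(cand, elements)
  d <- .pair_tss_distances(cand, genes)
  neg <- cand[d <= cutoff, c("element_id", "gene_id"), drop = FALSE]
  neg$label <- rep(0L, nrow(neg))
  rownames(neg) <- NULL
  attr(neg, "distance_cutoff") <- cutoff
  attr(neg, "percentile") <- percentile
  neg
}

#' Build a reference set from genetic-screen perturbation records
#'
#' Applies the screen filtering rules: records whose targeted element lies
#' less than `tss_exclusion` bp from any TSS (promoter-promoter
#' interactions) are removed entirely; of the rest, a record is a ground
#' positive when the perturbation was significant and associated with a
#' decrease in expression, and a ground negative otherwise (not significant,
#' or not a decrease).
#'
#' @param records data.frame with element coordinates (`chrom`, `start`,
#'   `end`), `element_id`, `gene_id`, `significant` (logical or 0/1) and
#'   `expression_effect` (signed fractional change, negative = decrease).
#' @param tss gene annotation or any table with `chrom` and `tss` columns.
#' @param tss_exclusion exclusion radius in bp (default 500, strict
#'   inequality, same gap convention as [min_tss_distance()]).
#' @return list with `pairs` (the labeled reference set) and `excluded`
#'   (the promoter-proximal records that were dropped).
#' @export
filter_criff <- function(records, tss, tss_exclusion = 500) {
  req <- c("chrom", "start", "end", "element_id", "gene_id", "significant",
           "expression_effect")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0)
    stop("screen records lack column(s): ", paste(miss, collapse = ", "))
  validate_intervals(records, "screen records")
  d <- vapply(seq_len(nrow(records)), function(i)
    .min_tss_distance_vec(records$chrom[i], records$start[i], records$end[i],
                          tss$chrom, tss$tss), numeric(1))
  drop <- d < tss_exclusion
  kept <- records[!drop, , drop = FALSE]
  pairs <- data.frame(
    element_id = kept$element_id, gene_id = kept$gene_id,
    label = as.integer(as.logical(kept$significant) &
                         kept$expression_effect < 0),
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  validate_reference_set(pairs, "screen reference set")
  list(pairs = pairs, excluded = records[drop, , drop = FALSE])
}

#' Build a prediction whitelist of regulatory regions
#'
#' The merged union of a cCRE catalog and of every TSS extended by `pad` bp
#' on each side; used to force a prediction method to consider all reference
#' elements.
#'
#' @param ccres interval data.frame of candidate cis-regulatory elements.
#' @param tss table with `chrom` and `tss` columns.
#' @param pad bp added on each side of a TSS (default 250).
#' @return merged interval data.frame.
#' @export
build_whitelist <- function(ccres, tss, pad = 250) {
  if (pad < 0) stop("pad must be nonnegative")
  tss_iv <- data.frame(chrom = tss$chrom,
                       start = pmax(tss$tss - pad, 0),
                       end = tss$tss + pad + 1,
                       stringsAsFactors = FALSE)
  ccres <- validate_intervals(ccres, "cCREs")
  merge_intervals(rbind(ccres[, c("chrom", "start", "end")],
                        tss_iv))
}
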