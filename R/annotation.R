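# Gene annotation: one row per TSS, columns gene_id, chrom, tss (0-based bp).
# A gene may have several TSSs; all distance computations use the nearest one.

#' Build a gene annotation table from a TSS BED file
#'
#' TSS files follow the BED convention of a 1 bp interval whose start is the
#' TSS; the 4th column carries the gene id.
#'
#' @param intervals interval data.frame as returned by [read_bed()].
#' @return data.frame with `gene_id`, `chrom`, `tss`.
#' @export
tss_from_bed <- function(intervals) {
  intervals <- validate_intervals(intervals, "TSS intervals")
  if (any(is.na(intervals$id)))
    stop("TSS records must carry a gene id in column 4")
  data.frame(gene_id = intervals$id, chrom = intervals$chrom,
             tss = intervals$start, stringsAsFactors = FALSE)
}

.check_gene_annotation <- function(genes) {
  miss <- setdiff(c("gene_id", "chrom", "tss"), names(genes))
  if (length(miss) > 0)
    stop("gene annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (any(genes$tss < 0)) stop("gene annotation: negative TSS position")
  invisible(genes)
}

# distance from each (element, gene) pair to the gene's nearest TSS.
# pairs must carry chrom/start/end of the element and gene_id; errors name
# genes absent from the annotation.
.pair_tss_distances <- function(pairs, genes) {
  .check_gene_annotation(genes)
  unknown <- setdiff(unique(pairs$gene_id), unique(genes$gene_id))
  if (length(unknown) > 0)
    stop("gene(s) absent from annotation: ", paste(unknown, collapse = ", "))
  tss_by_gene <- split(genes[, c("chrom", "tss")], genes$gene_id)
  vapply(seq_len(nrow(pairs)), function(i) {
    g <- tss_by_gene[[pairs$gene_id[i]]]
    .min_tss_distance_vec(pairs$chrom[i], pairs$start[i], pairs$end[i],
                          g$chrom, g$tss)
  }, numeric(1))
}

# attach element coordinates to an (element_id, gene_id) pair table
.join_elements <- function(pairs, elements) {
  elements <- validate_intervals(elements, "elements")
  idx <- match(pairs$element_id, elements$id)
  if (anyNA(idx))
    stop("element(s) absent from element table: ",
         paste(unique(pairs$element_id[is.na(idx)]), collapse = ", "))
  pairs$chrom <- elements$chrom[idx]
  pairs$start <- elements$start[idx]
  pairs$end <- elements$end[idx]
  pairs
}
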