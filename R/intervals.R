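#' @importFrom GenomicRanges GRanges reduce findOverlaps seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Intervals are plain data.frames in BED convention: 0-based start (inclusive),
# end exclusive, with optional `id` and `strand` columns. Strand is carried but
# ignored by all scoring.

.empty_intervals <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             id = character(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a set of genomic intervals
#'
#' Checks the invariants every interval in the package must satisfy:
#' non-empty chromosome name, `start >= 0`, `end > start`.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `id`, `strand`.
#' @param what label used in error messages.
#' @return The input, invisibly, with `id`/`strand` columns guaranteed present.
#' @export
validate_intervals <- function(intervals, what = "interval") {
  stopifnot(is.data.frame(intervals))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(intervals))
  if (length(miss) > 0)
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(intervals) > 0) {
    if (any(is.na(intervals$chrom)) || any(!nzchar(intervals$chrom)))
      stop(what, ": empty chromosome name")
    if (any(!is.finite(intervals$start)) || any(!is.finite(intervals$end)))
      stop(what, ": non-finite coordinates")
    if (any(intervals$start < 0))
      stop(what, ": negative start coordinate")
    if (any(intervals$end <= intervals$start))
      stop(what, ": end must exceed start (half-open convention)")
  }
  if (is.null(intervals$id)) intervals$id <- rep(NA_character_, nrow(intervals))
  if (is.null(intervals$strand)) intervals$strand <- rep(".", nrow(intervals))
  invisible(intervals)
}

# BED (0-based half-open) -> GRanges (1-based closed), chromosome levels sorted
# so that downstream reduce() output is ordered by (chrom, start).
.as_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = factor(intervals$chrom, levels = sort(unique(intervals$chrom))),
    ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
  )
}

#' Read genomic intervals from a BED file
#'
#' Parses BED3/BED4/BED6; the 4th column, when present, becomes the interval
#' `id` and the 6th the strand. Track/browser/comment lines are skipped.
#' Input order is preserved. Malformed records (fewer than 3 columns,
#' non-integer coordinates, `end <= start`) raise an error naming the
#' offending line number.
#'
#' @param path path to a tab-separated BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `id`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines))
  if (length(keep) == 0) return(.empty_intervals())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(n_col < 3)
  if (length(bad) > 0)
    stop("BED parse error at line ", keep[bad[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, character(1), 1)
  start_chr <- vapply(fields, `[[`, character(1), 2)
  end_chr <- vapply(fields, `[[`, character(1), 3)
  if (any(!grepl("^[0-9]+$", start_chr)) || any(!grepl("^[0-9]+$", end_chr))) {
    bad <- which(!grepl("^[0-9]+$", start_chr) | !grepl("^[0-9]+$", end_chr))[1]
    stop("BED parse error at line ", keep[bad], ": non-integer coordinates")
  }
  start <- as.numeric(start_chr)
  end <- as.numeric(end_chr)
  bad <- which(end <= start)
  if (length(bad) > 0)
    stop("BED parse error at line ", keep[bad[1]], ": end <= start")
  id <- ifelse(n_col >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                  character(1)), NA_character_)
  strand <- ifelse(n_col >= 6, vapply(fields, function(f) f[min(6, length(f))],
                                      character(1)), ".")
  validate_intervals(data.frame(chrom = chrom, start = start, end = end,
                                id = id, strand = strand,
                                stringsAsFactors = FALSE), what = path)
}

#' Write genomic intervals to a BED file
#'
#' Emits BED3 (or BED4/BED6 when `id`/non-"." strand are present), tab
#' separated with LF line endings.
#'
#' @param intervals interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  has_id <- any(!is.na(intervals$id))
  has_strand <- any(intervals$strand != ".")
  cols <- list(intervals$chrom, format(intervals$start, scientific = FALSE,
                                       trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE))
  if (has_id || has_strand)
    cols <- c(cols, list(ifelse(is.na(intervals$id), ".", intervals$id)))
  if (has_strand)
    cols <- c(cols, list("0", intervals$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), path, sep = "\n")
  invisible(path)
}

#' Merge overlapping and bookended intervals
#'
#' Concatenates, sorts and merges intervals in the sense of `bedtools merge`:
#' the output is sorted by (chrom, start), no two output intervals overlap or
#' abut, and the union of covered bases is preserved. Bookended intervals
#' (end of one equals start of the next) are merged.
#'
#' @param intervals interval data.frame; may be empty.
#' @return merged interval data.frame (ids are not propagated).
#' @export
merge_intervals <- function(intervals) {
  intervals <- validate_intervals(intervals)
  if (nrow(intervals) == 0) return(.empty_intervals())
  red <- GenomicRanges::reduce(.as_granges(intervals))
  validate_intervals(data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = GenomicRanges::end(red),
    id = NA_character_, strand = ".",
    stringsAsFactors = FALSE))
}

#' Map elements onto a catalog of candidate cis-regulatory elements
#'
#' Every element is mapped to all catalog intervals sharing at least one base
#' with it (half-open convention, so abutting intervals do not match). This is
#' the coordinate-to-cCRE-id conversion used when evaluating coordinate-based
#' prediction files against id-based reference sets.
#'
#' @param elements interval data.frame.
#' @param catalog interval data.frame with unique, non-missing `id`s.
#' @return named list, one character vector of catalog ids per element
#'   (empty vector when nothing overlaps); names are element ids where
#'   available, otherwise the element's position.
#' @export
intersect_with_catalog <- function(elements, catalog) {
  elements <- validate_intervals(elements, "elements")
  catalog <- validate_intervals(catalog, "catalog")
  if (any(is.na(catalog$id))) stop("catalog intervals must all carry an id")
  if (anyDuplicated(catalog$id)) stop("catalog ids must be unique")
  nm <- ifelse(is.na(elements$id), as.character(seq_len(nrow(elements))),
               elements$id)
  if (nrow(elements) == 0) return(stats::setNames(list(), character(0)))
  if (nrow(catalog) == 0)
    return(stats::setNames(rep(list(character(0)), nrow(elements)), nm))
  hits <- GenomicRanges::findOverlaps(.as_granges(elements),
                                      .as_granges(catalog), minoverlap = 1)
  out <- split(catalog$id[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits),
                      levels = seq_len(nrow(elements))))
  stats::setNames(lapply(out, as.character), nm)
}

#' Distance between an element and the nearest TSS of a gene
#'
#' Returns 0 when any TSS lies inside the half-open element span; otherwise
#' the positive gap between the TSS and the nearest covered base of the
#' element, minimised over the gene's TSSs. Different chromosomes yield `Inf`
#' (such a pair is never a candidate).
#'
#' @param element a single interval (one-row data.frame or list with `chrom`,
#'   `start`, `end`).
#' @param gene gene annotation rows for one gene: data.frame with `chrom` and
#'   `tss` columns (one row per TSS).
#' @return numeric distance in bp (possibly `Inf`).
#' @export
min_tss_distance <- function(element, gene) {
  stopifnot(length(element$chrom) == 1)
  if (nrow(gene) == 0) stop("gene has no TSS")
  .min_tss_distance_vec(element$chrom, element$start, element$end,
                        gene$chrom, gene$tss)
}

# vectorised core: one element vs many TSSs -> scalar min
.min_tss_distance_vec <- function(chrom, start, end, tss_chrom, tss) {
  same <- tss_chrom == chrom
  if (!any(same)) return(Inf)
  tss <- tss[same]
  d <- ifelse(tss >= start & tss < end, 0,
              ifelse(tss < start, start - tss, tss - (end - 1)))
  min(d)
}
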