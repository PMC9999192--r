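# The four E/G scoring methods. All take and return plain data.frames of
# candidate pairs; scores are added as named columns.

#' Score candidate pairs by inverse TSS distance
#'
#' The baseline distance method: the score of an (element, gene) pair is the
#' inverse of the smallest distance between the element and a TSS of the
#' gene. Distances are floored at `d_floor` so overlapping pairs get a finite
#' maximal score of `1 / d_floor`.
#'
#' @param pairs data.frame with `element_id`, `gene_id` and either element
#'   coordinates (`chrom`, `start`, `end`) or an `elements` table to join.
#' @param genes gene annotation (`gene_id`, `chrom`, `tss`).
#' @param elements optional interval table supplying element coordinates.
#' @param d_floor distance floor in bp (default 1).
#' @return `pairs` with columns `tss_distance` and `distance_score` added.
#' @export
score_distance <- function(pairs, genes, elements = NULL, d_floor = 1) {
  if (!is.null(elements)) pairs <- .join_elements(pairs, elements)
  d <- .pair_tss_distances(pairs, genes)
  pairs$tss_distance <- d
  pairs$distance_score <- 1 / pmax(d, d_floor)
  pairs
}

#' Score candidate pairs by accessibility/expression correlation
#'
#' The Sheffield method: Pearson correlation between the log10 chromatin
#' accessibility at the element and the log10 expression of the gene across
#' a shared panel of cell types. A pseudocount is added before logging.
#' Pairs whose accessibility or expression vector has zero variance get an
#' `NA` correlation (undefined); such pairs rank below all defined values
#' downstream. A two-sided t-test p-value and a Fisher z-score are reported
#' alongside `correlation`, but only the correlation drives ranking.
#'
#' @param pairs data.frame with `element_id` and `gene_id`.
#' @param accessibility signal matrix, rows = element ids.
#' @param expression signal matrix, rows = gene ids.
#' @param pseudocount added before log10 (default 1).
#' @return `pairs` with `correlation`, `correlation_p`, `correlation_z` added.
#' @export
score_sheffield <- function(pairs, accessibility, expression, pseudocount = 1) {
  validate_signal_matrix(accessibility, "accessibility")
  validate_signal_matrix(expression, "expression")
  if (!identical(colnames(accessibility), colnames(expression)))
    stop("accessibility and expression must share an identical ordered cell-type list")
  n <- ncol(accessibility)
  if (n < 3) stop("need >= 3 cell types for correlation scoring")
  miss_e <- setdiff(unique(pairs$element_id), rownames(accessibility))
  if (length(miss_e) > 0)
    stop("element(s) absent from accessibility matrix: ",
         paste(miss_e, collapse = ", "))
  miss_g <- setdiff(unique(pairs$gene_id), rownames(expression))
  if (length(miss_g) > 0)
    stop("gene(s) absent from expression matrix: ",
         paste(miss_g, collapse = ", "))
  la <- log10(accessibility[pairs$element_id, , drop = FALSE] + pseudocount)
  le <- log10(expression[pairs$gene_id, , drop = FALSE] + pseudocount)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- la[i, ]; y <- le[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  pairs$correlation <- r
  # two-sided t approximation and Fisher z, as reported by the original script
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pairs$correlation_p <- 2 * stats::pt(abs(tstat), df = n - 2,
                                       lower.tail = FALSE)
  pairs$correlation_z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)) *
    sqrt(n - 3)
  pairs
}

# descending-score ranks, ties sharing the mean of the tied positions;
# NAs (undefined scores) rank below every defined value, mid-ranked among
# themselves.
.rank_desc <- function(x) {
  r <- numeric(length(x))
  ok <- !is.na(x)
  r[ok] <- rank(-x[ok], ties.method = "average")
  if (any(!ok)) r[!ok] <- sum(ok) + (sum(!ok) + 1) / 2
  r
}

#' Combine distance and correlation ranks into the Average-Rank score
#'
#' Each pair is ranked (1 = best, i.e. largest score) separately under the
#' distance score and under the correlation; the Average-Rank score is the
#' inverse of the mean of the two ranks. Ranking is within the supplied
#' candidate set. Tied scores share the mean of the tied rank positions;
#' undefined correlations rank last. Rows are returned sorted by
#' (element_id, gene_id) so output order is deterministic.
#'
#' @param pairs data.frame carrying `distance_score` and `correlation`.
#' @return `pairs` with `distance_rank`, `correlation_rank`, `average_rank`
#'   and `average_rank_score` added.
#' @export
score_average_rank <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  miss <- setdiff(c("distance_score", "correlation"), names(pairs))
  if (length(miss) > 0)
    stop("pairs lack required score(s): ", paste(miss, collapse = ", "))
  pairs <- pairs[order(pairs$element_id, pairs$gene_id), , drop = FALSE]
  pairs$distance_rank <- .rank_desc(pairs$distance_score)
  pairs$correlation_rank <- .rank_desc(pairs$correlation)
  pairs$average_rank <- (pairs$distance_rank + pairs$correlation_rank) / 2
  pairs$average_rank_score <- 1 / pairs$average_rank
  rownames(pairs) <- NULL
  pairs
}

#' Activity of a candidate element
#'
#' Geometric mean of the chromatin-accessibility and H3K27ac read counts at
#' the element, with an optional pseudocount added to each count first.
#'
#' @param accessibility_count,h3k27ac_count nonnegative read counts
#'   (vectorised).
#' @param pseudocount `c0 >= 0` added to each count (default 0).
#' @return activity values `sqrt((acc + c0) * (h3k27ac + c0))`.
#' @export
abc_activity <- function(accessibility_count, h3k27ac_count, pseudocount = 0) {
  if (any(accessibility_count < 0) || any(h3k27ac_count < 0))
    stop("read counts must be nonnegative")
  sqrt((accessibility_count + pseudocount) * (h3k27ac_count + pseudocount))
}

#' Build a contact model
#'
#' Contact between an element and a gene is either taken from a table of
#' normalized contact frequencies or modelled as the inverse of the
#' element-TSS distance (fractal globule distance decay).
#'
#' @param mode `"distance_decay"` or `"table"`.
#' @param table for table mode: data.frame with `element_id`, `gene_id`,
#'   `contact` (nonnegative).
#' @param d_floor distance floor in bp for decay mode (default 1).
#' @return an object of class `contact_model`.
#' @export
contact_model <- function(mode = c("distance_decay", "table"), table = NULL,
                          d_floor = 1) {
  mode <- match.arg(mode)
  if (mode == "table") {
    if (is.null(table)) stop("table mode needs a contact table")
    miss <- setdiff(c("element_id", "gene_id", "contact"), names(table))
    if (length(miss) > 0)
      stop("contact table lacks column(s): ", paste(miss, collapse = ", "))
    if (any(table$contact < 0)) stop("contact values must be nonnegative")
  }
  structure(list(mode = mode, table = table, d_floor = d_floor),
            class = "contact_model")
}

#' Contact between elements and a gene under a contact model
#'
#' Decay mode returns `1 / max(distance, d_floor)`; table mode returns the
#' stored contact, 0 for pairs absent from the table.
#'
#' @param elements interval data.frame with `id`s.
#' @param gene a one-gene annotation (rows of a gene table sharing one
#'   `gene_id`).
#' @param model a [contact_model()].
#' @return numeric contact per element.
#' @export
abc_contact <- function(elements, gene, model) {
  stopifnot(inherits(model, "contact_model"))
  elements <- validate_intervals(elements, "elements")
  if (model$mode == "distance_decay") {
    d <- vapply(seq_len(nrow(elements)), function(i)
      .min_tss_distance_vec(elements$chrom[i], elements$start[i],
                            elements$end[i], gene$chrom, gene$tss),
      numeric(1))
    return(1 / pmax(d, model$d_floor))
  }
  key <- paste(model$table$element_id, model$table$gene_id, sep = "\r")
  idx <- match(paste(elements$id, gene$gene_id[1], sep = "\r"), key)
  ifelse(is.na(idx), 0, model$table$contact[idx])
}

#' Activity-By-Contact scores of candidate elements for one gene
#'
#' The ABC score of element E for gene G is A(E) * C(E,G) divided by the sum
#' of the same product over all candidate elements within a `window` of G
#' (read as a window centered on the gene's nearest TSS, i.e. elements within
#' `window / 2` of it). Scores over in-window elements sum to 1 whenever any
#' product is positive; if every product is 0 all scores are 0. Elements
#' outside the window get score `NA`.
#'
#' @param elements interval data.frame with `id`, `accessibility_count` and
#'   `h3k27ac_count` columns.
#' @param gene one-gene annotation rows (`gene_id`, `chrom`, `tss`).
#' @param model a [contact_model()].
#' @param window total window size in bp around the TSS (default 5e6).
#' @param pseudocount activity pseudocount `c0` (default 0).
#' @return data.frame with `element_id`, `activity`, `contact`, `abc_score`.
#' @export
score_abc <- function(elements, gene, model, window = 5e6, pseudocount = 0) {
  if (window <= 0) stop("window must be positive")
  elements <- validate_intervals(elements, "elements")
  d <- vapply(seq_len(nrow(elements)), function(i)
    .min_tss_distance_vec(elements$chrom[i], elements$start[i],
                          elements$end[i], gene$chrom, gene$tss), numeric(1))
  in_win <- d <= window / 2
  if (!any(in_win))
    stop("no candidate element within the window of gene ", gene$gene_id[1])
  a <- abc_activity(elements$accessibility_count, elements$h3k27ac_count,
                    pseudocount)
  cc <- abc_contact(elements, gene, model)
  prod <- a * cc
  denom <- sum(prod[in_win])
  score <- rep(NA_real_, nrow(elements))
  score[in_win] <- if (denom > 0) prod[in_win] / denom else 0
  data.frame(element_id = elements$id, activity = a, contact = cc,
             abc_score = score, stringsAsFactors = FALSE)
}

#' Filter genes by expression or promoter activity
#'
#' The ABC model predicts links only for expressed genes; when expression is
#' unavailable, promoter activity (accessibility x H3K27ac at the promoter)
#' serves as a proxy. Keeps genes whose chosen signal is at least `threshold`.
#'
#' @param gene_ids character vector of gene ids.
#' @param expression named numeric vector of expression values, or NULL.
#' @param promoter_activity named numeric vector of promoter activities,
#'   used for genes missing from `expression`.
#' @param threshold minimal signal to keep a gene.
#' @return character vector of retained gene ids (input order).
#' @export
filter_expressed_genes <- function(gene_ids, expression = NULL,
                                   promoter_activity = NULL, threshold = 0) {
  signal <- vapply(gene_ids, function(g) {
    if (!is.null(expression) && g %in% names(expression)) return(expression[[g]])
    if (!is.null(promoter_activity) && g %in% names(promoter_activity))
      return(promoter_activity[[g]])
    stop("gene ", g, " has neither expression nor promoter activity")
  }, numeric(1))
  gene_ids[signal >= threshold]
}
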