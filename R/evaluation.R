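# Precision-recall evaluation: curves, AUPR (average-precision integration)
# and the thresholded point metrics with pessimistic/optimistic recall.

#' Precision-recall curve of scored, labeled pairs
#'
#' Thresholds sweep the distinct score values in descending order; at each
#' threshold every pair scoring at least that value is called positive
#' (tied scores enter together). Undefined (`NA`) scores sort below all
#' defined values. Requires at least one positive label.
#'
#' @param scored data.frame with `score` and `label` (0/1) columns.
#' @return data.frame of class `pr_curve` with columns `threshold`,
#'   `precision`, `recall`, and attributes `positives` / `negatives`.
#' @export
pr_curve <- function(scored) {
  stopifnot(all(c("score", "label") %in% names(scored)))
  if (!all(scored$label %in% c(0, 1))) stop("labels must be 0/1")
  P <- sum(scored$label == 1)
  if (P == 0) stop("no positive labels: recall undefined")
  s <- ifelse(is.na(scored$score), -Inf, scored$score)
  o <- order(s, decreasing = TRUE)
  s <- s[o]; lab <- scored$label[o]
  tp <- cumsum(lab == 1)
  n_called <- seq_along(lab)
  last_of_run <- cumsum(rle(s)$lengths)    # last index of each tied block
  out <- data.frame(threshold = s[last_of_run],
                    precision = tp[last_of_run] / n_called[last_of_run],
                    recall = tp[last_of_run] / P)
  attr(out, "positives") <- P
  attr(out, "negatives") <- sum(scored$label == 0)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Area under a precision-recall curve
#'
#' Step-wise integration over recall increments using the precision at the
#' right endpoint of each step — the average-precision convention.
#' Trapezoidal integration is deliberately not used as it overestimates PR
#' areas.
#'
#' @param curve a [pr_curve()].
#' @return area in `[0, 1]`.
#' @export
aupr <- function(curve) {
  stopifnot(inherits(curve, "pr_curve") ||
              all(c("precision", "recall") %in% names(curve)))
  r <- curve$recall
  sum((r - c(0, r[-length(r)])) * curve$precision)
}

#' Point metrics with pessimistic and optimistic recall
#'
#' From a thresholded prediction set matched against a reference:
#' precision = TP / predicted, pessimistic recall = TP / all reference
#' positives, optimistic recall = TP / reference positives present in the
#' prediction universe. Percentages are reported raw and rounded for display
#' (precision to 1 decimal, recalls to 2). Zero denominators yield `NA`.
#'
#' @param tp true positives.
#' @param n_predicted positive predictions matched to any reference pair
#'   (TP + FP); must be >= `tp`.
#' @param gp_pes total reference positives.
#' @param gp_opt reference positives within the prediction universe.
#' @return one-row data.frame with counts, raw percentages
#'   (`precision_pct_raw`, `recall_pes_pct_raw`, `recall_opt_pct_raw`) and
#'   display-rounded percentages (`precision_pct`, `recall_pes_pct`,
#'   `recall_opt_pct`).
#' @export
point_metrics <- function(tp, n_predicted, gp_pes, gp_opt) {
  if (any(c(tp, n_predicted, gp_pes, gp_opt) < 0)) stop("counts must be >= 0")
  if (tp > n_predicted) stop("tp cannot exceed n_predicted")
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  prec <- pct(tp, n_predicted)
  rpes <- pct(tp, gp_pes)
  ropt <- pct(tp, gp_opt)
  data.frame(tp = tp, n_predicted = n_predicted, gp_pes = gp_pes,
             gp_opt = gp_opt,
             precision_pct_raw = prec, recall_pes_pct_raw = rpes,
             recall_opt_pct_raw = ropt,
             precision_pct = round(prec, 1),
             recall_pes_pct = round(rpes, 2),
             recall_opt_pct = round(ropt, 2))
}

# map coordinate-based predictions to (catalog id, gene id) pairs:
# enhancer -> overlapping cCRE ids, promoter -> genes whose TSS it covers.
.map_predictions <- function(predictions, ccres, tss) {
  enh <- data.frame(chrom = predictions$chrom, start = predictions$start,
                    end = predictions$end, stringsAsFactors = FALSE)
  hits <- intersect_with_catalog(enh, ccres)
  .check_gene_annotation(tss)
  out <- vector("list", nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    on <- tss$chrom == predictions$prom_chrom[i] &
      tss$tss >= predictions$prom_start[i] &
      tss$tss < predictions$prom_end[i]
    gids <- unique(tss$gene_id[on])
    cids <- hits[[i]]
    if (length(cids) == 0 || length(gids) == 0) next
    out[[i]] <- data.frame(
      element_id = rep(cids, times = length(gids)),
      gene_id = rep(gids, each = length(cids)),
      predicted = predictions$predicted[i], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(element_id = character(0), gene_id = character(0),
                      predicted = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Evaluate a thresholded prediction set against a labeled reference
#'
#' Predictions may already be id-resolved (`element_id`, `gene_id`,
#' `predicted` 0/1) or coordinate-based (enhancer `chrom`/`start`/`end` and
#' promoter `prom_chrom`/`prom_start`/`prom_end`), in which case `ccres` and
#' `tss` are used to convert coordinates into catalog/gene ids. Counting is
#' over distinct mapped pairs: TP = positive predictions matching a label-1
#' reference pair; the precision denominator is positive predictions matching
#' any reference pair; the optimistic-recall denominator is reference
#' positives present anywhere in the mapped prediction universe (positive or
#' negative predictions alike).
#'
#' @param predictions prediction data.frame (see above); a missing
#'   `predicted` column means every row is a positive prediction.
#' @param reference labeled reference set (`element_id`, `gene_id`, `label`).
#' @param ccres,tss catalog and TSS annotation, required for
#'   coordinate-based predictions.
#' @return a [point_metrics()] row.
#' @export
evaluate_predictions <- function(predictions, reference, ccres = NULL,
                                 tss = NULL) {
  validate_reference_set(reference)
  if (nrow(reference) == 0) stop("reference set is empty")
  if (is.null(predictions$predicted)) predictions$predicted <- 1L
  if (!all(c("element_id", "gene_id") %in% names(predictions))) {
    if (is.null(ccres) || is.null(tss))
      stop("coordinate-based predictions need ccres and tss")
    predictions <- .map_predictions(predictions, ccres, tss)
  }
  key <- function(df) paste(df$element_id, df$gene_id, sep = "\r")
  universe <- unique(key(predictions))
  pos_pred <- unique(key(predictions[predictions$predicted == 1, ,
                                     drop = FALSE]))
  ref1 <- key(reference[reference$label == 1, , drop = FALSE])
  ref_all <- key(reference)
  point_metrics(tp = sum(pos_pred %in% ref1),
                n_predicted = sum(pos_pred %in% ref_all),
                gp_pes = length(ref1),
                gp_opt = sum(ref1 %in% universe))
}
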