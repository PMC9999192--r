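# Labeled element/gene pair files: 3 tab-separated columns (element id,
# gene id, 0/1 label), no header; a 4th column may carry a method score.

#' Validate a labeled reference set of element/gene pairs
#'
#' Labels must be 0/1 and no (element, gene) pair may appear with both labels.
#'
#' @param pairs data.frame with `element_id`, `gene_id`, `label` (and
#'   optionally `score`).
#' @param what label for error messages.
#' @return the input, invisibly.
#' @export
validate_reference_set <- function(pairs, what = "reference set") {
  req <- c("element_id", "gene_id", "label")
  miss <- setdiff(req, names(pairs))
  if (length(miss) > 0)
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(pairs) > 0) {
    if (!all(pairs$label %in% c(0, 1)))
      stop(what, ": labels must be 0 or 1")
    key <- paste(pairs$element_id, pairs$gene_id, sep = "\r")
    lab_per_key <- tapply(pairs$label, key, function(x) length(unique(x)))
    if (any(lab_per_key > 1))
      stop(what, ": pair ",
           sub("\r", "/", names(lab_per_key)[lab_per_key > 1][1]),
           " appears with conflicting labels")
  }
  invisible(pairs)
}

#' Read a labeled pair file
#'
#' @param path tab-separated file: element id, gene id, label, optional score.
#' @return data.frame with `element_id`, `gene_id`, `label` and, when a 4th
#'   column is present, `score`.
#' @export
read_pair_file <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("pair file needs >= 3 columns: ", path)
  out <- data.frame(element_id = as.character(df[[1]]),
                    gene_id = as.character(df[[2]]),
                    label = df[[3]], stringsAsFactors = FALSE)
  if (!all(out$label %in% c(0L, 1L)))
    stop("pair file ", path, ": labels must parse as 0/1")
  out$label <- as.integer(out$label)
  if (ncol(df) >= 4) out$score <- as.numeric(df[[4]])
  validate_reference_set(out, path)
  out
}

#' Write a labeled pair file
#'
#' Tab separated, LF line endings, no header; a `score` column, when present,
#' is written as a 4th column. `read_pair_file(write_pair_file(x))` is the
#' identity.
#'
#' @param pairs validated pair data.frame.
#' @param path output path.
#' @export
write_pair_file <- function(pairs, path) {
  validate_reference_set(pairs)
  cols <- list(pairs$element_id, pairs$gene_id, pairs$label)
  if (!is.null(pairs$score))
    cols <- c(cols, list(format(pairs$score, scientific = FALSE, trim = TRUE)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path, sep = "\n")
  invisible(path)
}
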