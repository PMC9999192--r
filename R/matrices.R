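# Signal matrices: numeric matrix, rownames = feature ids (peaks, cCREs or
# genes), colnames = cell types. All values nonnegative and finite.

#' Validate a feature-by-cell-type signal matrix
#'
#' @param m numeric matrix with unique rownames (feature ids) and colnames
#'   (cell types); values nonnegative and finite.
#' @param what label for error messages.
#' @return the matrix, invisibly.
#' @export
validate_signal_matrix <- function(m, what = "signal matrix") {
  if (!is.matrix(m) || !is.numeric(m)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " needs feature ids (rownames) and cell types (colnames)")
  if (anyDuplicated(rownames(m))) stop(what, ": duplicate feature ids")
  if (anyDuplicated(colnames(m))) stop(what, ": duplicate cell types")
  if (any(!is.finite(m))) stop(what, ": non-finite values")
  if (any(m < 0)) stop(what, ": negative values")
  invisible(m)
}

#' Read a signal matrix from TSV
#'
#' Expects a header row of cell-type names and a first column of feature ids,
#' the layout of multi-cell-type accessibility/expression tables.
#'
#' @param path path to a tab-separated file.
#' @return validated numeric matrix (features x cell types).
#' @export
read_signal_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("signal matrix needs >= 1 cell-type column: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validate_signal_matrix(m, path)
  m
}

#' Write a signal matrix to TSV
#'
#' @param m validated signal matrix.
#' @param path output path.
#' @param feature_col name of the leading id column in the header.
#' @export
write_signal_matrix <- function(m, path, feature_col = "feature") {
  validate_signal_matrix(m)
  header <- paste(c(feature_col, colnames(m)), collapse = "\t")
  body <- apply(m, 1, function(row)
    paste(format(row, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(c(header, paste(rownames(m), body, sep = "\t")), path, sep = "\n")
  invisible(path)
}
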