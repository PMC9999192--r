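# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own code paths (per-base occupancy,
# all-pairs loops, textbook formulas) so that agreement is informative.

# interval union via per-base occupancy, re-segmented into maximal runs
oracle_merge <- function(intervals) {
  out <- list()
  for (ch in sort(unique(intervals$chrom))) {
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    covered <- sort(unique(unlist(mapply(
      function(s, e) seq(s, e - 1), sub$start, sub$end, SIMPLIFY = FALSE))))
    run_start <- covered[c(TRUE, diff(covered) > 1)]
    run_end <- covered[c(diff(covered) > 1, TRUE)] + 1
    out[[ch]] <- data.frame(chrom = ch, start = run_start, end = run_end,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# all-pairs overlap test (half-open)
oracle_overlap <- function(elements, catalog) {
  lapply(seq_len(nrow(elements)), function(i) {
    hit <- catalog$chrom == elements$chrom[i] &
      catalog$start < elements$end[i] & catalog$end > elements$start[i]
    catalog$id[hit]
  })
}

# textbook Pearson correlation from sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

# average-precision identity: mean over positives of precision at their rank
oracle_ap <- function(score, label) {
  o <- order(score, decreasing = TRUE)
  lab <- label[o]
  ks <- which(lab == 1)
  sum(cumsum(lab)[ks] / ks) / sum(lab)
}

# PR points by recounting the confusion table at every distinct threshold
oracle_pr <- function(score, label) {
  thr <- sort(unique(score), decreasing = TRUE)
  data.frame(threshold = thr,
             precision = vapply(thr, function(t)
               sum(label == 1 & score >= t) / sum(score >= t), numeric(1)),
             recall = vapply(thr, function(t)
               sum(label == 1 & score >= t) / sum(label == 1), numeric(1)))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 2000,
                             max_width = 120) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

pair_key <- function(df, cols = c("element_id", "gene_id")) {
  sort(do.call(paste, c(df[cols], sep = "/")))
}
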