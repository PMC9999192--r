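genes3 <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
                     tss = c(1500, 2500, 11000), stringsAsFactors = FALSE)
el3 <- data.frame(chrom = "chr1", start = c(1000, 1000, 1000),
                  end = c(2000, 2000, 2000), id = c("E1", "E2", "E3"),
                  stringsAsFactors = FALSE)

test_that("score_distance inverts the floored minimal TSS distance", {
  pairs <- data.frame(element_id = "E1", gene_id = "G2",
                      stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "G2", chrom = "chr1", tss = 2500)
  got <- score_distance(pairs, genes,
                        elements = el3[1, ])
  expect_equal(got$distance_score, 1 / 501)
  # a distance of exactly 500
  genes$tss <- 2499
  expect_equal(score_distance(pairs, genes, elements = el3[1, ])$distance_score,
               1 / 500)
  # overlap -> floored at 1
  genes$tss <- 1500
  expect_equal(score_distance(pairs, genes, elements = el3[1, ])$distance_score,
               1)
})

test_that("score_distance is strictly monotone in distance and flags unknown genes", {
  pairs <- data.frame(element_id = c("E1", "E2", "E3"),
                      gene_id = c("G1", "G2", "G3"), stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
                      tss = c(2009, 2099, 2999))  # distances 10, 100, 1000
  got <- score_distance(pairs, genes, elements = el3)
  expect_equal(got$distance_score, c(0.1, 0.01, 0.001))
  expect_true(all(diff(got$distance_score) < 0))
  expect_error(score_distance(pairs, genes[1:2, ], elements = el3), "G3")
})

test_that("score_sheffield computes Pearson r of logged signals", {
  acc <- matrix(c(1, 10, 100, 1000), nrow = 1,
                dimnames = list("E1", paste0("c", 1:4)))
  expr <- matrix(c(2, 20, 200, 2000), nrow = 1,
                 dimnames = list("G1", paste0("c", 1:4)))
  pairs <- data.frame(element_id = "E1", gene_id = "G1",
                      stringsAsFactors = FALSE)
  got <- score_sheffield(pairs, acc, expr, pseudocount = 0)
  expect_equal(got$correlation, 1)

  # zero-variance expression -> undefined sentinel
  expr0 <- matrix(rep(5, 4), nrow = 1,
                  dimnames = list("G1", paste0("c", 1:4)))
  expect_true(is.na(score_sheffield(pairs, acc, expr0)$correlation))

  # textbook Pearson on the logged vectors as oracle
  acc2 <- matrix(c(3, 1, 4, 1, 5), nrow = 1,
                 dimnames = list("E1", paste0("c", 1:5)))
  expr2 <- matrix(c(9, 2, 6, 5, 3), nrow = 1,
                  dimnames = list("G1", paste0("c", 1:5)))
  got <- score_sheffield(pairs, acc2, expr2, pseudocount = 1)
  expect_equal(got$correlation,
               oracle_pearson(log10(c(3, 1, 4, 1, 5) + 1),
                              log10(c(9, 2, 6, 5, 3) + 1)))
  expect_true(got$correlation_p >= 0 && got$correlation_p <= 1)

  # mismatched cell-type lists and missing rows are errors
  colnames(expr2) <- paste0("d", 1:5)
  expect_error(score_sheffield(pairs, acc2, expr2), "cell-type")
  expect_error(score_sheffield(data.frame(element_id = "EX", gene_id = "G1"),
                               acc2, acc2), "EX")
})

test_that("global rescaling leaves the correlation unchanged at pseudocount 0", {
  set.seed(11)
  acc <- matrix(10^runif(8, 1, 3), nrow = 1,
                dimnames = list("E1", paste0("c", 1:8)))
  expr <- matrix(10^runif(8, 1, 3), nrow = 1,
                 dimnames = list("G1", paste0("c", 1:8)))
  pairs <- data.frame(element_id = "E1", gene_id = "G1",
                      stringsAsFactors = FALSE)
  r0 <- score_sheffield(pairs, acc, expr, pseudocount = 0)$correlation
  r1 <- score_sheffield(pairs, acc * 37, expr * 37,
                        pseudocount = 0)$correlation
  expect_equal(r1, r0, tolerance = 1e-12)
  # with a pseudocount the deviation vanishes as counts grow
  dev <- function(k) {
    abs(score_sheffield(pairs, acc * k, expr * k, pseudocount = 1)$correlation -
          score_sheffield(pairs, acc * k * 37, expr * k * 37,
                          pseudocount = 1)$correlation)
  }
  expect_lt(dev(1e6), dev(1))
  expect_lt(dev(1e6), 1e-6)
})

test_that("score_average_rank inverts the mean of the two ranks", {
  pairs <- data.frame(element_id = c("E1", "E2"), gene_id = c("G1", "G2"),
                      distance_score = c(2, 1), correlation = c(0.9, 0.1),
                      stringsAsFactors = FALSE)
  got <- score_average_rank(pairs)
  expect_equal(got$average_rank_score, c(1, 0.5))

  # anti-correlated ranks give identical scores
  pairs3 <- data.frame(element_id = c("E1", "E2", "E3"),
                       gene_id = c("G1", "G2", "G3"),
                       distance_score = c(3, 2, 1),
                       correlation = c(0.1, 0.5, 0.9),
                       stringsAsFactors = FALSE)
  got <- score_average_rank(pairs3)
  expect_equal(got$average_rank_score[c(1, 3)], c(0.5, 0.5))
})

test_that("score_average_rank matches a brute-force mean-rank sort and is rank-invariant", {
  set.seed(21)
  pairs <- data.frame(element_id = sprintf("E%02d", 1:20),
                      gene_id = sprintf("G%02d", 1:20),
                      distance_score = runif(20), correlation = runif(20),
                      stringsAsFactors = FALSE)
  got <- score_average_rank(pairs)
  # independent ranking oracle: position in descending sort, no package code
  brute_rank <- function(x) match(seq_along(x), order(x, decreasing = TRUE))
  want <- (brute_rank(pairs$distance_score) +
             brute_rank(pairs$correlation)) / 2
  expect_equal(got$average_rank[match(pairs$element_id, got$element_id)], want)
  expect_equal(order(got$average_rank_score, decreasing = TRUE),
               order(got$average_rank))

  # invariance under strictly monotone transforms of either input
  tr <- pairs
  tr$distance_score <- exp(tr$distance_score)
  tr$correlation <- tr$correlation^3
  expect_equal(score_average_rank(tr)$average_rank_score,
               got$average_rank_score)
})

test_that("undefined correlations rank last in Average-Rank", {
  pairs <- data.frame(element_id = c("E1", "E2", "E3"),
                      gene_id = c("G1", "G2", "G3"),
                      distance_score = c(3, 2, 1),
                      correlation = c(0.5, NA, 0.9),
                      stringsAsFactors = FALSE)
  got <- score_average_rank(pairs)
  expect_equal(got$correlation_rank[got$element_id == "E2"], 3)
})

test_that("abc_activity is the geometric mean of the counts", {
  expect_equal(abc_activity(4, 16), 8)
  expect_equal(abc_activity(0, 100), 0)
  expect_equal(abc_activity(7, 13, pseudocount = 1), sqrt(8 * 14))
  expect_error(abc_activity(-1, 5), "nonnegative")
})

test_that("abc_contact covers decay and table modes", {
  el <- data.frame(chrom = "chr1", start = 1000, end = 2000, id = "E1",
                   stringsAsFactors = FALSE)
  gene <- data.frame(gene_id = "G1", chrom = "chr1", tss = 2999)
  expect_equal(abc_contact(el, gene, contact_model("distance_decay")),
               0.001)
  tab <- data.frame(element_id = "E1", gene_id = "G1", contact = 7.5,
                    stringsAsFactors = FALSE)
  expect_equal(abc_contact(el, gene, contact_model("table", tab)), 7.5)
  gene2 <- data.frame(gene_id = "G2", chrom = "chr1", tss = 2999)
  expect_equal(abc_contact(el, gene2, contact_model("table", tab)), 0)
})

test_that("score_abc normalizes activity-contact products over the window", {
  gene <- data.frame(gene_id = "G1", chrom = "chr1", tss = 50000)
  one <- data.frame(chrom = "chr1", start = 10000, end = 10500, id = "E1",
                    accessibility_count = 10, h3k27ac_count = 40,
                    stringsAsFactors = FALSE)
  got <- score_abc(one, gene, contact_model("distance_decay"))
  expect_equal(got$abc_score, 1)

  two <- rbind(one, one)
  two$id <- c("E1", "E2")
  expect_equal(score_abc(two, gene, contact_model("distance_decay"))$abc_score,
               c(0.5, 0.5))

  # five elements with stated activities and contacts, hand-normalized
  five <- data.frame(chrom = "chr1",
                     start = c(1000, 20000, 40000, 60000, 80000),
                     end = c(1500, 20500, 40500, 60500, 80500),
                     id = sprintf("E%d", 1:5),
                     accessibility_count = c(4, 9, 16, 25, 0),
                     h3k27ac_count = c(16, 9, 4, 1, 5),
                     stringsAsFactors = FALSE)
  tab <- data.frame(element_id = sprintf("E%d", 1:5), gene_id = "G1",
                    contact = c(2, 1, 0.5, 0.25, 10),
                    stringsAsFactors = FALSE)
  got <- score_abc(five, gene, contact_model("table", tab))
  prod <- c(8 * 2, 9 * 1, 8 * 0.5, 5 * 0.25, 0 * 10)
  expect_equal(got$abc_score, prod / sum(prod))
  expect_equal(sum(got$abc_score), 1)

  expect_error(score_abc(five, gene, contact_model("table", tab),
                         window = 0), "window")
  far_gene <- data.frame(gene_id = "G9", chrom = "chr2", tss = 1)
  expect_error(score_abc(five, far_gene, contact_model("distance_decay")),
               "window")
})

test_that("all-zero activity-contact products give all-zero scores", {
  gene <- data.frame(gene_id = "G1", chrom = "chr1", tss = 50000)
  el <- data.frame(chrom = "chr1", start = c(10000, 20000),
                   end = c(10500, 20500), id = c("E1", "E2"),
                   accessibility_count = c(0, 0), h3k27ac_count = c(5, 7),
                   stringsAsFactors = FALSE)
  got <- score_abc(el, gene, contact_model("distance_decay"))
  expect_equal(got$abc_score, c(0, 0))
})

test_that("filter_expressed_genes thresholds expression or its promoter proxy", {
  ids <- c("G1", "G2", "G3")
  expr <- c(G1 = 0, G2 = 5, G3 = 30)
  expect_equal(filter_expressed_genes(ids, expression = expr, threshold = 0),
               ids)
  expect_equal(filter_expressed_genes(ids, expression = expr, threshold = 20),
               "G3")
  # promoter-activity proxy used for genes without expression
  set.seed(3)
  ids10 <- sprintf("G%02d", 1:10)
  act <- stats::setNames(runif(10, 0, 50), ids10)
  expect_equal(filter_expressed_genes(ids10, promoter_activity = act,
                                      threshold = 25),
               ids10[act >= 25])
  expect_error(filter_expressed_genes("GX", expression = expr), "GX")
})
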