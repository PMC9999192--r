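# Seeded generator of a toy regulatory genome with known enhancer/gene
# wiring, so every scoring method and the evaluation harness can be run and
# validated offline.

#' Configuration of the synthetic regulatory genome
#'
#' Defaults describe a small two-chromosome genome whose full pipeline run
#' (generation, all four scorings, evaluation) completes in seconds.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes,n_elements number of genes (one TSS each) and candidate
#'   elements.
#' @param n_cell_types number of cell types in the signal matrices.
#' @param wiring_prob probability that an element within
#'   `max_wiring_distance` of a gene's TSS is a true enhancer of it.
#' @param max_wiring_distance maximal element-TSS distance of a true
#'   (wired) pair, in bp.
#' @param candidate_distance maximal element-TSS distance of a labeled
#'   candidate pair (the truth-set universe); pairs beyond
#'   `max_wiring_distance` but within this window are guaranteed negatives.
#' @param signal_effect shared-activation amplitude (log10 units) coupling a
#'   true enhancer's accessibility to its target's expression.
#' @param noise_sd log10-scale noise standard deviation.
#' @param contact_decay_floor distance floor (bp) of the contact table's
#'   1/distance decay.
#' @param element_width element width in bp.
#' @param min_tss_clearance minimal element-TSS gap enforced at placement.
#' @param seed integer master seed; every random stream derives from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 2, chrom_length = 1e7,
                             n_genes = 60, n_elements = 400,
                             n_cell_types = 30, wiring_prob = 0.3,
                             max_wiring_distance = 1e5,
                             candidate_distance = 5e5, signal_effect = 2,
                             noise_sd = 0.25, contact_decay_floor = 5000,
                             element_width = 500, min_tss_clearance = 1000,
                             seed = 1) {
  cfg <- list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              n_genes = n_genes, n_elements = n_elements,
              n_cell_types = n_cell_types, wiring_prob = wiring_prob,
              max_wiring_distance = max_wiring_distance,
              candidate_distance = candidate_distance,
              signal_effect = signal_effect, noise_sd = noise_sd,
              contact_decay_floor = contact_decay_floor,
              element_width = element_width,
              min_tss_clearance = min_tss_clearance, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_chromosomes >= 1, n_genes >= 1, n_elements >= 1,
              n_cell_types >= 1, chrom_length > 0,
              wiring_prob >= 0, wiring_prob <= 1,
              max_wiring_distance > 0,
              candidate_distance >= max_wiring_distance,
              signal_effect >= 0, noise_sd > 0,
              contact_decay_floor >= 1, element_width >= 1)
  })
  structure(cfg, class = "synthetic_config")
}

# independent sub-stream per generation stage: adding a new output file never
# perturbs the randomness of existing ones
.stage_seed <- function(seed, stage) {
  set.seed((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)
}

#' Generate a synthetic regulatory genome bundle
#'
#' Places genes and elements uniformly (elements never closer than
#' `min_tss_clearance` to a TSS); wires each element to each gene within
#' `max_wiring_distance` with probability `wiring_prob`. Per cell type t a
#' latent activation `a[E,t] ~ N(0,1)` drives both sides of a true pair:
#' wired elements get `log10 accessibility = base_E + signal_effect * a[E,t]
#' + noise` and a wired gene's `log10 expression = base_G + signal_effect *
#' mean(a over its true enhancers) + noise`; unwired features get
#' independent noise. H3K27ac tracks accessibility with extra noise; the
#' contact table decays as 1/max(distance, floor) with multiplicative
#' lognormal jitter. Count matrices are integer (rounded exp of the log
#' signals). The truth set labels wired pairs 1 and every other pair within
#' `candidate_distance` 0. Identical configs yield identical bundles.
#'
#' @param config a [synthetic_config()].
#' @return list with `genes`, `elements`, `accessibility`, `expression`,
#'   `h3k27ac`, `contacts`, `truth`, `config`.
#' @export
generate_regulatory_genome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config

  # --- placement -----------------------------------------------------------
  .stage_seed(cfg$seed, 1)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  genes <- data.frame(
    gene_id = sprintf("G%03d", seq_len(cfg$n_genes)),
    chrom = sample(chroms, cfg$n_genes, replace = TRUE),
    tss = floor(stats::runif(cfg$n_genes, cfg$min_tss_clearance,
                             cfg$chrom_length - cfg$min_tss_clearance)),
    stringsAsFactors = FALSE)
  place_one <- function() {
    for (try in 1:1000) {
      ch <- sample(chroms, 1)
      s <- floor(stats::runif(1, 0, cfg$chrom_length - cfg$element_width))
      d <- .min_tss_distance_vec(ch, s, s + cfg$element_width,
                                 genes$chrom, genes$tss)
      if (d >= cfg$min_tss_clearance) return(c(ch, s))
    }
    stop("could not place elements clear of TSSs after 1000 tries; ",
         "increase chrom_length")
  }
  placed <- vapply(seq_len(cfg$n_elements), function(i) place_one(),
                   character(2))
  elements <- data.frame(
    chrom = placed[1, ], start = as.numeric(placed[2, ]),
    end = as.numeric(placed[2, ]) + cfg$element_width,
    id = sprintf("E%04d", seq_len(cfg$n_elements)), strand = ".",
    stringsAsFactors = FALSE)

  # --- candidate pairs and wiring -----------------------------------------
  d_mat <- outer(seq_len(cfg$n_elements), seq_len(cfg$n_genes),
                 Vectorize(function(i, j)
                   .min_tss_distance_vec(elements$chrom[i], elements$start[i],
                                         elements$end[i], genes$chrom[j],
                                         genes$tss[j])))
  cand <- which(d_mat <= cfg$candidate_distance, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  .stage_seed(cfg$seed, 2)
  wired <- stats::rbinom(nrow(cand), 1, cfg$wiring_prob) == 1 &
    d_mat[cand] <= cfg$max_wiring_distance
  truth <- data.frame(element_id = elements$id[cand[, 1]],
                      gene_id = genes$gene_id[cand[, 2]],
                      label = as.integer(wired), stringsAsFactors = FALSE)

  # --- signals -------------------------------------------------------------
  .stage_seed(cfg$seed, 3)
  latent <- matrix(stats::rnorm(cfg$n_elements * cfg$n_cell_types),
                   nrow = cfg$n_elements)
  base_e <- stats::runif(cfg$n_elements, 1.5, 2.5)
  base_g <- stats::runif(cfg$n_genes, 1.0, 2.0)
  cells <- sprintf("CT%02d", seq_len(cfg$n_cell_types))

  element_wired <- elements$id %in% truth$element_id[truth$label == 1]
  .stage_seed(cfg$seed, 4)
  log_acc <- base_e + cfg$signal_effect * latent * element_wired +
    matrix(stats::rnorm(cfg$n_elements * cfg$n_cell_types, sd = cfg$noise_sd),
           nrow = cfg$n_elements)
  accessibility <- round(10^log_acc)
  dimnames(accessibility) <- list(elements$id, cells)

  enh_of <- split(match(truth$element_id[truth$label == 1], elements$id),
                  truth$gene_id[truth$label == 1])
  .stage_seed(cfg$seed, 5)
  gene_act <- t(vapply(genes$gene_id, function(g) {
    w <- enh_of[[g]]
    if (is.null(w)) rep(0, cfg$n_cell_types)
    else colMeans(latent[w, , drop = FALSE])
  }, numeric(cfg$n_cell_types)))
  log_expr <- base_g + cfg$signal_effect * gene_act +
    matrix(stats::rnorm(cfg$n_genes * cfg$n_cell_types, sd = cfg$noise_sd),
           nrow = cfg$n_genes)
  expression <- round(10^log_expr)
  dimnames(expression) <- list(genes$gene_id, cells)

  .stage_seed(cfg$seed, 6)
  h3k27ac <- round(10^(log_acc +
    matrix(stats::rnorm(cfg$n_elements * cfg$n_cell_types, sd = cfg$noise_sd),
           nrow = cfg$n_elements)))
  dimnames(h3k27ac) <- list(elements$id, cells)

  # --- contacts ------------------------------------------------------------
  .stage_seed(cfg$seed, 7)
  d_cand <- d_mat[cand]
  contacts <- data.frame(
    element_id = truth$element_id, gene_id = truth$gene_id,
    contact = (1 / pmax(d_cand, cfg$contact_decay_floor)) *
      stats::rlnorm(nrow(truth), meanlog = 0, sdlog = 0.25),
    stringsAsFactors = FALSE)

  list(genes = genes, elements = elements,
       accessibility = accessibility, expression = expression,
       h3k27ac = h3k27ac, contacts = contacts, truth = truth, config = cfg)
}

#' Write a synthetic bundle to a directory
#'
#' Emits exactly the plain-text formats the rest of the package reads:
#' `tss.bed`, `elements.bed`, `accessibility.tsv`, `expression.tsv`,
#' `h3k27ac.tsv`, `contacts.tsv` and `truth.pairs`.
#'
#' @param bundle a [generate_regulatory_genome()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- bundle$genes
  write_bed(data.frame(chrom = g$chrom, start = g$tss, end = g$tss + 1,
                       id = g$gene_id, strand = ".",
                       stringsAsFactors = FALSE),
            file.path(dir, "tss.bed"))
  write_bed(bundle$elements, file.path(dir, "elements.bed"))
  write_signal_matrix(bundle$accessibility,
                      file.path(dir, "accessibility.tsv"), "element")
  write_signal_matrix(bundle$expression, file.path(dir, "expression.tsv"),
                      "gene")
  write_signal_matrix(bundle$h3k27ac, file.path(dir, "h3k27ac.tsv"),
                      "element")
  ct <- bundle$contacts
  writeLines(paste(ct$element_id, ct$gene_id,
                   format(ct$contact, scientific = FALSE, trim = TRUE,
                          digits = 15),
                   sep = "\t"),
             file.path(dir, "contacts.tsv"), sep = "\n")
  write_pair_file(bundle$truth, file.path(dir, "truth.pairs"))
  invisible(dir)
}

#' Score every truth-set pair of a bundle with all four methods
#'
#' Runs the distance, correlation (Sheffield), Average-Rank and
#' Activity-By-Contact scorings on the bundle's candidate pairs. ABC uses
#' per-element total accessibility and H3K27ac counts (summed over cell
#' types) as activity inputs and the bundle's contact table as contacts.
#'
#' @param bundle a [generate_regulatory_genome()] result.
#' @param pseudocount log pseudocount for the correlation scoring.
#' @param window ABC window in bp.
#' @return the truth pairs with `distance_score`, `correlation`,
#'   `average_rank_score` and `abc_score` columns added.
#' @export
score_truth_pairs <- function(bundle, pseudocount = 1, window = 5e6) {
  pairs <- bundle$truth
  pairs <- score_distance(pairs, bundle$genes, elements = bundle$elements)
  pairs <- score_sheffield(pairs, bundle$accessibility, bundle$expression,
                           pseudocount = pseudocount)
  pairs <- score_average_rank(pairs)

  el <- bundle$elements
  el$accessibility_count <- rowSums(bundle$accessibility)[el$id]
  el$h3k27ac_count <- rowSums(bundle$h3k27ac)[el$id]
  model <- contact_model("table", table = bundle$contacts)
  pairs$abc_score <- NA_real_
  for (g in unique(pairs$gene_id)) {
    gene <- bundle$genes[bundle$genes$gene_id == g, , drop = FALSE]
    abc <- score_abc(el, gene, model, window = window)
    sel <- pairs$gene_id == g
    sc <- abc$abc_score[match(pairs$element_id[sel], abc$element_id)]
    pairs$abc_score[sel] <- ifelse(is.na(sc), 0, sc)
  }
  pairs
}

#' Per-method AUPR on the synthetic truth set
#'
#' The synthetic counterpart of a benchmark's per-method precision-recall
#' summary: each score column is evaluated against the truth labels.
#'
#' @param bundle a [generate_regulatory_genome()] result.
#' @param scores scored truth pairs (defaults to [score_truth_pairs()]);
#'   must carry `label` and the columns named in `methods`.
#' @param methods named or plain character vector of score columns.
#' @return data.frame with `method`, `aupr` and `prevalence`.
#' @export
truth_recovery_report <- function(bundle, scores = NULL,
                                  methods = c("distance_score", "correlation",
                                              "average_rank_score",
                                              "abc_score")) {
  if (is.null(scores)) scores <- score_truth_pairs(bundle)
  miss <- setdiff(c("label", methods), names(scores))
  if (length(miss) > 0)
    stop("scores lack column(s): ", paste(miss, collapse = ", "))
  prev <- mean(scores$label == 1)
  res <- vapply(methods, function(m)
    aupr(pr_curve(data.frame(score = scores[[m]], label = scores$label))),
    numeric(1))
  data.frame(method = methods, aupr = unname(res), prevalence = prev,
             stringsAsFactors = FALSE)
}
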