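---
title: "Scoring and benchmarking enhancer/gene links"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and benchmarking enhancer/gene links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egbench)
```

## The problem

An enhancer/gene (E/G) link is the claim that a distal open-chromatin
element E activates the expression of gene G in some cell type. Methods that
infer such links from 1D functional data are cheap and genome-wide, but they
disagree with each other, and they can only be judged against reference sets
that are themselves imperfect — 3D-contact and eQTL derived sets are
genome-wide but noisy, CRISPR-interference screens are reliable but cover a
handful of loci in one cell line. `egbench` implements both sides of this
comparison: the scoring methods and the evaluation machinery, over plain
data.frames and plain-text formats (BED intervals, TSV signal matrices,
3/4-column pair files).

All coordinates are 0-based half-open (BED convention); a TSS file is a 1 bp
interval whose start is the TSS. Strand is carried but ignored: none of the
scoring methods is strand-aware. Distance between an element and a TSS is 0
on overlap and otherwise the gap to the nearest covered base — so an element
`[1000, 2000)` is 501 bp from a TSS at 2500. The same convention is used
everywhere a distance or an exclusion radius appears.

## The scoring methods

**Distance.** `score_distance()` returns 1/max(d, 1) where d is the distance
to the gene's nearest TSS. The 1 bp floor keeps the score finite for
TSS-overlapping elements without disturbing the ordering elsewhere.

**Sheffield correlation.** `score_sheffield()` computes Pearson *r* between
log10(accessibility + 1) at E and log10(expression + 1) of G across a shared
ordered panel of at least three cell types. The +1 pseudocount is the
standard convention for count data and is configurable. Pairs whose logged
accessibility or expression vector is constant have no defined correlation
and carry an `NA` sentinel; every consumer in the package ranks these below
all defined values. A two-sided t-approximation p-value and a Fisher
z-score are reported alongside *r*, but only *r* is ever used for ranking.

**Average-Rank.** `score_average_rank()` ranks the candidate set twice — by
distance score and by correlation, rank 1 being best — and scores each pair
as the inverse of its mean rank. Ties share the mean of the tied positions
(mid-rank), which makes the score invariant under any strictly monotone
transform of either input. Ranking is performed within the supplied
candidate set: whether the original method ranks genome-wide or per
evaluation set is not documented anywhere we know of, and per-set ranking is
the only choice that keeps evaluation sets independent of each other. Rows
are returned in deterministic (element, gene) order.

**ABC.** The Activity-By-Contact score of element E for gene G is

$$\mathrm{ABC}(E,G) = \frac{A(E)\,C(E,G)}{\sum_{e \in W(G)} A(e)\,C(e,G)}$$

with activity $A$ the geometric mean of accessibility and H3K27ac read
counts (`abc_activity()`, optional pseudocount, default 0 so that a zero
count annihilates the activity, as a geometric mean should), contact $C$
either a supplied normalized contact table (absent pairs contribute 0) or
the 1/distance fractal-globule decay (`abc_contact()`), and $W(G)$ the
candidate elements within a 5 Mb window around G — read as ±2.5 Mb around
the gene's nearest TSS, the convention of the method's reference
implementation, and configurable. In-window scores sum to exactly 1 whenever
any activity–contact product is positive; a degenerate all-zero window
yields all-zero scores rather than 0/0. `filter_expressed_genes()` restricts
predictions to expressed genes, accepting either expression values or
promoter activity as a proxy.

**The correlation caller.** `call_correlation_pairs()` reproduces the
classic open-chromatin heuristic end to end: per-cell-type peak sets are
merged into consensus peaks (`merge_intervals()`, bookended intervals merge,
as in `bedtools merge`); per-peak counts are normalized by each cell type's
total mapped reads in peaks; same-chromosome peak pairs closer than 500 kb
(gap between nearest covered bases, strict) are correlated on the
log10(+ pseudocount) scale; pairs with *r* strictly above 0.7 where one peak
covers a gene TSS become calls of (other peak, that gene). When both peaks
of a pair cover TSSs each anchors a call for the other — the symmetric
reading of the rule. Both thresholds and the pseudocount live in
`correlation_call_config()`.

## Reference sets

`make_bengi_negatives()` implements the distance-matched negative rule: the
95th percentile (type-7 linear interpolation; recorded in the output
attributes so other conventions can be compared) of the positive pairs'
element–TSS distances defines a cutoff, and every (positive-set enhancer,
annotated gene) pair within the cutoff that is not itself positive becomes a
negative. Distances use the gene's nearest TSS, consistent with the distance
method; the percentile is computed per positive set.

`filter_criff()` turns perturbation-screen records into a labeled set:
records whose element lies strictly less than 500 bp from any TSS are
excluded outright (promoter–promoter interactions), and the remainder are
positive exactly when significant *and* associated with an expression
decrease. The three groups partition the input.

`build_whitelist()` merges a cCRE catalog with TSSs padded by 250 bp on each
side, the region set on which a prediction method can be forced to make
calls.

## Evaluation

`pr_curve()` sweeps the distinct score values in descending order, tied
scores entering together; the loosest threshold always lands at
(precision = prevalence, recall = 1). `aupr()` integrates step-wise over
recall increments using the right-endpoint precision — average-precision
semantics. Trapezoidal integration is deliberately avoided: linear
interpolation between PR points is not achievable by any thresholding of the
classifier and systematically overestimates the area.

For thresholded (binary) prediction files only a single precision/recall
point is computable, and recall is reported twice: pessimistically
(TP / all reference positives) and optimistically (TP / reference positives
that the prediction universe could have found). `evaluate_predictions()`
derives the four counts from a prediction file — mapping coordinates to
catalog ids via `intersect_with_catalog()` and promoters to genes via TSS
overlap, counting distinct mapped pairs — and `point_metrics()` turns counts
into percentages, reported raw and display-rounded (precision to 1 decimal,
recalls to 2, matching how such tables are conventionally printed).

## The synthetic regulatory genome

`generate_regulatory_genome()` emulates the multi-cell-type inputs of the
methods above with known ground truth. The default configuration — 2
chromosomes × 10 Mb, 60 genes, 400 elements of 500 bp, 30 cell types —
keeps a full generate–score–evaluate cycle under a minute on one core and
yields roughly 1,200 labeled candidate pairs at ~6% prevalence.

Placement is uniform with a 1 kb exclusion zone around TSSs (an element
overlapping a promoter would confound every distance-anchored method);
placement failure after bounded retries raises an error suggesting a longer
chromosome. Each element wires to each gene within `max_wiring_distance`
(default 100 kb, the scale at which most validated enhancer–gene pairs sit)
with probability `wiring_prob` (default 0.3). The labeled universe is wider:
every pair within `candidate_distance` (default 500 kb, the standard
cis-candidate window also used by the correlation caller) is labeled, so
negatives include both unwired nearby genes and all genes between 100 kb and
500 kb. Separating the wiring range from the candidate range is what gives
the distance method a realistic, non-trivial signal — positives concentrate
at short range while negatives spread over the whole window; collapsing the
two ranges would make distance uninformative by construction.

Signals live on the log10 scale: element baselines Uniform(1.5, 2.5) (about
30–300 reads), gene baselines Uniform(1, 2), i.i.d. Gaussian noise of sd
`noise_sd` (default 0.25). A per-element, per-cell-type latent activation
a ~ N(0,1) is amplified by `signal_effect` (default 2) in wired elements'
accessibility, and a wired gene's expression receives the mean latent of its
true enhancers — so a true pair co-varies across cell types exactly the way
the Sheffield method assumes. H3K27ac follows accessibility with independent
noise of the same sd. The contact table covers the candidate pairs with
1/max(d, 5 kb) decay times lognormal jitter (sdlog 0.25); 5 kb is a typical
contact-map resolution. Counts are rounded powers of ten of the log signals,
so matrices are integer read counts. All randomness flows from one master
seed through per-stage sub-streams, making bundles byte-identical across
runs and stable under the addition of new output types.

What the generator does *not* emulate: mappability and GC biases, shared
enhancers with cell-type-specific wiring, repressive elements, overlapping
genes, multi-TSS isoform structure, and the heavy-tailed peak-width and
expression distributions of real data. Recovery results on this genome
validate the implementation of each method — that each score ranks planted
signal above noise — not the methods' relative merits on real chromatin.

## Numerical choices and edge cases

- Quantiles are type-7; ranks are mid-rank on ties; undefined correlations
  rank last.
- Inverse-distance scores floor the distance at 1 bp.
- Strict inequalities follow their sources: correlation calls require
  *r* > 0.7 and gap < 500 kb; promoter exclusion is gap < 500 bp.
- `pr_curve()` requires at least one positive (recall is undefined
  otherwise); zero denominators in point metrics yield `NA`, never 0 or an
  error.
- The test suite checks every interval operation against per-base occupancy
  or all-pairs brute-force oracles, AUPR against the average-precision
  identity, and the generator against permutation nulls; problem sizes there
  (≤1,000 pairs, 20 replicates of the default genome) were chosen to make
  those exhaustive oracles exact yet fast.

## Limitations

The package evaluates and compares scoring methods; it does not train
supervised link classifiers, call peaks from alignments, or balance Hi-C
matrices — count matrices, peak sets and contact tables are consumed, not
produced. Thresholded third-party prediction files can be evaluated but not
re-scored, which is precisely why the pessimistic/optimistic recall pair
exists.
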