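Package: egbench
Title: Scoring and Benchmarking of Enhancer-Gene Regulatory Links
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting and benchmarking enhancer/gene (E/G)
    regulatory links from functional genomic data. Implements four scoring
    methods (inverse TSS distance, Sheffield-style accessibility/expression
    correlation across cell types, Average-Rank, and the Activity-By-Contact
    model), an open-chromatin pairwise-correlation link caller, construction
    of labeled reference sets (BENGI-style distance-matched negatives,
    CRISPRi-FlowFISH screen filtering, prediction whitelists), and a
    precision-recall evaluation harness with AUPR and pessimistic/optimistic
    point metrics. A seeded generator of a toy regulatory genome with known
    E/G wiring lets the whole pipeline run and be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
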