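Package: glocerna
Title: Functional ceRNA Pair Identification from Matched Tumor-Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies functional lncRNA-mediated competing endogenous RNA
    (ceRNA) pairs from normal/tumor matched expression cohorts by combining
    per-sample differential-expression direction consistency (the DEC score)
    with cohort-wide Pearson correlation of relative (log2 fold-change)
    expression. Includes construction of candidate lncRNA-PCG pairs from
    miRNA-target interaction tables, bipartite ceRNA network topology,
    hypergeometric cancer-hallmark enrichment, Kaplan-Meier/log-rank survival
    screening with mean-expression dichotomization, super-enhancer and typical
    enhancer gene assignment, THZ1-sensitivity classification, and a
    synthetic-data generator with planted ground truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    survival,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
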