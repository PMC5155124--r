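Package: dcgn
Title: Differentially Coexpressed Gene Ranking from Phase-Specific
    Coexpression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate disease genes from time-series expression
    data by quantifying how each gene's local network neighbourhood changes
    between phase-specific weighted gene coexpression networks. Implements
    two per-gene differential-coexpression scores -- a topological
    dissimilarity of k-level neighbourhood edge sets (DCGN-S) and a variation
    of local topological information derived from random-walk transition
    probabilities (DCGN-I) -- together with soft-threshold network
    construction, rank-product aggregation across network pairs, ROC/AUC
    evaluation against labelled gene sets, fold-change and t-statistic
    rank-product baselines, and a synthetic-data generator with planted
    rewired genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
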