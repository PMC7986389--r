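Package: wmfvs
Title: Weight-Aware Feedback Vertex Sets for Directed Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact solvers and evaluation tools for weighted feedback vertex
    set problems on directed graphs, motivated by cancer-gene prioritisation
    in directed protein interaction networks. Implements MFVS-preserving
    graph compression with forced-vertex extraction, ordering-formulation
    integer programs for the minimum feedback vertex set, the maximum-weight
    MFVS and weight-driven FVSs (penalty and negative-shift variants) solved
    by a verified exact branch-and-bound, differential-expression vertex
    weighting from tumour/normal expression matrices, shuffled-weight
    permutation null ensembles with empirical p-values, enrichment scores
    and dark-gene analysis, and synthetic generators with exhaustive
    brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
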