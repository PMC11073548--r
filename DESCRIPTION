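Package: topofilt
Title: Topological Inference on Weighted Networks via Graph Filtration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Persistent-homology analysis of weighted networks restricted to
    the graph filtration (1-skeleton). Decomposes a weighted graph's edge
    weights into a birth set (maximum spanning forest, the 0D persistence
    diagram) and a death set (remaining edges, the 1D diagram) with a
    union-find Kruskal pass, computes Betti-0/Betti-1 curves over filtration
    thresholds, and measures 2-Wasserstein-type distances between networks
    through order-matched sorted births and deaths. Group differences are
    tested with a between/within distance ratio statistic under permutation
    and online transposition resampling, and with a parametric Z-statistic on
    between- versus within-group distances. Includes leave-one-out jackknife
    construction of structural covariance networks from subject-by-node
    feature tables, seeded synthetic generators (noisy point-cloud circle
    patterns, weight-matched trees, factor-model feature tables), delimited
    text input/output, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
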