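Package: coregscan
Title: Signed Gene Co-Regulation Networks and Classifier Threshold Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers signed gene co-regulation networks from relative
    expression tables (qPCR delta-Ct scale) by crossing a Spearman rank
    correlation test with a permutation-calibrated mutual information test,
    quantifies differences between two networks with an integer edge
    distance, and sweeps a candidate classifier gene's expression threshold
    to find the sample split that produces maximally different networks.
    Includes a synthetic-cohort generator with planted dependence regimes
    for power and recovery studies, and a command-line interface for the
    full stratify-infer-distance-scan workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
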