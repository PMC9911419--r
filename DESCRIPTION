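Package: cobinet
Title: Network-Guided Differential Co-Expression Biclustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially co-expressed gene modules (biclusters) in
    expression matrices by screening gene-interaction-network edges with
    rank-rank hypergeometric overlap (RRHO) and signal-to-noise-ratio scoring,
    grouping the surviving edges into modules with a collapsed Gibbs sampler
    for a finite Bernoulli mixture over edge-by-sample membership indicators,
    and merging candidate modules with Fisher exact tests under sample-size
    and signal-to-noise constraints. Includes a planted-module simulation
    benchmark with matched gene networks and cell-level Jaccard evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
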