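Package: netpharm
Title: Graph-Theoretic Analysis of Pharmacologically Induced Brain Network
    Reconfiguration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying drug-induced reconfiguration of functional
    brain networks from regional time series. Builds Fisher-z connectivity
    matrices, binarizes them by proportional density thresholding, computes
    binary graph metrics (clustering, characteristic path length, global and
    local efficiency, small-worldness against degree-preserving null
    ensembles) and a census of the eight connected undirected 3-4-node
    motifs, summarizes metric curves across a density grid as areas under
    the curve, and performs group inference with paired or two-sample
    t-tests under false discovery rate control plus edge-level Network
    Based Statistics with permutation family-wise error control. A
    synthetic-data module emulates paired cross-over and two-group designs
    with modular latent covariance, temporal autocorrelation, and planted
    topological effects, so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
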