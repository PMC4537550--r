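Package: ringscore
Title: Shape-Agnostic Periodicity Scoring of Expression Time Series via
    Sliding-Window Persistent Homology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies periodicity in gene-expression time series without
    assuming a signal shape. A signal is embedded as a sliding-window
    (time-delay) point cloud, pointwise mean-centered and normalized onto
    the unit sphere, and its circularity is measured with 1-dimensional
    persistent homology of the Vietoris-Rips filtration; the coverage
    radius b and the maximal death d combine into a score in [0,1]
    (0 = periodic, 1 = not periodic). Includes a synthetic benchmark
    generator (14 signal shapes, four variance-matched noise models,
    three sampling densities), permutation significance testing, and a
    ROC/AUC evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
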