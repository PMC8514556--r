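Package: crosssort
Title: Convergent Cross Sorting for Estimating Dynamic Coupling from Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the existence, direction, and relative strength of dynamic
    coupling between time series using Convergent Cross Sorting (CCS), a
    state-space-reconstruction method that tests for a correspondence between the
    ranks of pairwise distances in the delay embeddings of two variables, together
    with a convergent cross mapping (CCM) baseline. Includes simulators for coupled
    Van der Pol oscillators, logistic maps, and autoregressive models on
    transitive-free network topologies with measurement and dynamical noise; an
    evaluation harness (detection ROC AUC, relative-strength Spearman correlation,
    unidirectional sweeps); and a sliding-window network-state analysis
    (windowed coupling vectors, PCA, k-means states, cyclic sequence statistics).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
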