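Package: nirsnet
Title: Small-World Functional Brain Networks from Multichannel fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for graph-theoretic analysis of functional brain
    networks measured with multichannel functional near-infrared spectroscopy
    (fNIRS). Oxyhemoglobin time series are band-pass filtered, segmented into
    peri-stimulus epochs and normalized; channels become network nodes and
    Pearson correlations between channels become edges. Correlation matrices
    are binarized over a sweep of thresholds and characterized by the
    clustering coefficient, average shortest path length, average node degree
    and the small-worldness measure computed against degree-preserving
    Markov-chain (double-edge-swap) random reference ensembles. Group-level
    curves are compared with two-sample t-tests at every threshold. A seeded
    synthetic-data generator emulating block-design fNIRS recordings with a
    group-dependent spatial correlation structure makes the full pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
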