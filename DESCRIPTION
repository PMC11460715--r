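Package: denseFC
Title: Dense-Sampling Single-Subject Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates day-by-day functional brain connectivity from
    densely sampled single-subject fMRI recordings and relates it to daily
    behavioral and physiological factors. Provides post-preprocessing signal
    conditioning (Savitzky-Golay detrending, confound regression,
    discrete-cosine high-pass filtering, motion scrubbing), per-session
    Pearson and beta-series adjacency estimation with Fisher stabilization
    and motion residualization, maximum-spanning-tree anchored proportional
    thresholding with participation coefficient and within-network global
    efficiency, permutation regression with Benjamini-Hochberg false
    discovery rate control, surrogate-calibrated lagged cross-correlation,
    inter-day representational similarity analysis with Mantel tests, and
    leave-one-session-out time-segment classification. A synthetic-data
    generator with known ground truth supports calibration and
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
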