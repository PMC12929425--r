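Package: plonet
Title: Polyploidy and the Structure of Plant-Pollinator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-level analysis of how the frequency of polyploid
    plants relates to the architecture of weighted plant-pollinator
    networks. Provides readers and validators for interaction matrices and
    plant trait tables; bipartite structural indices (connectance, weighted
    NODF nestedness, Barber modularity with a weighted label-propagation
    optimizer); robustness to plant extinction including ploidy-targeted
    removal orders; fixed-marginal null models with delta standardization
    of every index; network-level trait frequencies and cohort filters;
    univariate regressions with a residual spatial autocorrelation test;
    a piecewise structural equation model with d-separation adequacy
    testing and direct/indirect effect decomposition; and a synthetic
    community generator with known ground truth for calibration and
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
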