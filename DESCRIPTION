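Package: wirecon
Title: Generative Network Models of Structural Connectomes Under an
    Economic Wiring Trade-Off
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the formation of binary, spatially embedded brain
    networks from a sparse seed under a probabilistic trade-off between
    wiring cost (an inter-nodal distance penalty, exponent eta) and
    topological value (homophily, clustering or degree terms, exponent
    gamma).  Provides the four consensus/thresholding procedures used to
    build group and participant modelling targets from weighted
    connectome stacks, Kolmogorov-Smirnov energy, topological-fingerprint
    and spatial-embedding model-fit criteria with grid-search and
    cumulative-rank model selection, Maslov-Sneppen degree-preserving
    nulls, cohort-level statistics linking fitted wiring parameters to
    polygenic scores, stochasticity experiments for softened wiring
    penalties, and permutation partial-least-squares decoding of nodal
    model terms against regional gene expression.  A synthetic-data
    module generates connectome cohorts with known ground-truth
    parameters, polygenic scores with a planted effect size, and
    spatially autocorrelated expression matrices, so the full pipeline
    runs without restricted neuroimaging or transcriptomic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
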