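Package: dcovnet
Title: Directed Functional Connectivity from Haemodynamic Time Series via
    Differential Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates directed functional connectivity from BOLD-like
    neural time series using differential covariance (the covariance
    between a node's temporal derivative and other nodes' signals),
    together with its partialled and sparse-latent regularized variants,
    and benchmarks them against covariance, precision, regularized
    precision and conditional Granger causality estimators.  Includes
    backward reconstruction of neural activity through a linearized
    Balloon-Windkessel haemodynamic model, autoregressive-bootstrap edge
    significance testing, comparison of functional and structural
    connectivity via structural-connectivity-strength statistics, binary
    graph topology measures for directed and undirected networks, and
    behavioural correlation analysis with confound regression.  A
    synthetic-data toolkit generates ground-truth networks, linear
    stochastic neural dynamics, haemodynamic forward simulations,
    surrogate structural connectomes and surrogate behaviour tables so
    the full pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    generics,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    igraph,
    optparse,
    yaml,
    signal
Config/testthat/edition: 3
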