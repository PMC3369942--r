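Package: sarcsim
Title: Agent-Based Simulation of Sarcomeric Pattern Formation in Actomyosin Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-dimensional agent-based model of an actomyosin bundle in which
    treadmilling actin filaments condense, via processive plus-end crosslinking,
    into polarity-sorted clusters (I-Z-I complexes) that coalesce and
    self-organize into periodic, sarcomere-like order. Bipolar myosin filaments
    act as dynamic, polarity-specific crosslinkers with a linear force-velocity
    relation; per time step the overdamped force balance over all mobile units
    is solved exactly. Includes structure-factor (Bragg peak) order parameters,
    cluster and spacing statistics, exponential-saturation time-scale fits, a
    stochastic filament-severing model of length control together with the
    numerical solution of its stationary length distribution, scenario presets,
    parameter scans, and plain-text trajectory input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
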