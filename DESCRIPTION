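Package: boutlaw
Title: Power-Law Versus Multi-Exponential Bout-Duration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and statistical-testing toolkit for deciding when
    power-law and multi-exponential bout-duration distributions mimic one
    another, motivated by sleep-wake architecture analysis. Provides seeded
    generators for truncated power-law, exponential-mixture and two-state
    Markov bout processes; power-law maximum-likelihood fitting with a fixed
    lower threshold; constrained multi-exponential nonlinear least-squares
    fitting of unit-width frequency-duration histograms; a parametric-bootstrap
    Kolmogorov-Smirnov goodness-of-fit test; an ordinary-least-squares
    log-log counter-method; Vuong's non-nested likelihood-ratio test; and
    parameter-sweep drivers that map the "zone of mimicry" across sample
    sizes and decay constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
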