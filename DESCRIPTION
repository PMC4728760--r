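Package: dynmix
Title: Dynamic Mixed-Effects Prediction Models for Clustered Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation framework for dynamically updated
    linear mixed-effects prediction models in clustered (multi-centre)
    populations. Generates clustered populations with heterogeneous
    cluster effects and a volume-outcome relationship, fits static and
    periodically refit ("dynamic") prediction models by penalized
    restricted maximum likelihood with empirical-Bayes cluster effects,
    and quantifies calibration through mean absolute error and the
    relative-improvement metric, including within-cluster learning
    curves and Monte-Carlo experiment grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    lme4,
    optparse,
    withr,
    yaml,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
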