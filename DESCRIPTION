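Package: sbridge
Title: Brain State Transition Costs via the Schrodinger Bridge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the cost of steering a stochastic system between
    distributions over discrete brain states. Activity time series are
    coarse-grained into k states by cosine (spherical) k-means, a baseline
    Markov transition kernel is estimated from resting-state sequences with
    trajectory bootstrapping, and the minimum Kullback-Leibler control cost
    between an initial and a target state distribution is obtained by solving
    the discrete Schrodinger Bridge endpoint problem with a log-domain
    Sinkhorn iteration. Includes condition-pair cost matrices, transition-cost
    asymmetry analysis, bootstrap significance tests, and a fully synthetic
    data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
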