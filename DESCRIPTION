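Package: labopt
Title: Bayesian Optimization of Laboratory Process Recipes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential model-based (Bayesian) optimization for expensive
    real-world experiments driven through an ask/tell interface. Supports
    mixed real/integer/categorical design spaces with mixture and
    value constraints, Latin-hypercube initial designs, a Gaussian-process
    surrogate (anisotropic Matern-5/2 kernel with learned observation
    noise), expected-improvement/probability-of-improvement/lower-confidence-bound
    acquisition, constant-liar batch suggestions, NSGA-II multi-objective
    search, and a benchmarking harness with pluggable noise models,
    including a synthetic universal pH-indicator colour plate scored by
    CIE76 Delta-E in CIELAB space. A small command-line front end drives
    long-running physical campaigns from a durable config + observation log.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lhs,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
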