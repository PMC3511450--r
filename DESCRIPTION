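Package: cflopt
Title: Constrained Fuzzy Logic Modeling of Signal Transduction Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains logic models of protein signal transduction pathways against
    single-time-point perturbation data using constrained fuzzy logic. Reactions
    carry normalized Hill transfer functions whose gain and midpoint parameters
    are fitted by bounded quasi-Newton optimization with multistart, minimizing
    the measurement-prediction mismatch over a prior knowledge network simulated
    at pseudo steady state. Includes network reduction by equivalent-class
    compartmentalization and iterative reaction pruning, cross-validation of the
    fitting procedure, SIF and MIDAS-dialect input/output, and synthetic fixture
    generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
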