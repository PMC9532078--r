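Package: sparrowforge
Title: Chaos-Enhanced Sparrow Search Optimization for Neural-Network
    Clinical Risk Models
Version: 0.1.0
Authors@R:
    person("Sparrowforge", "Developers", email = "sparrowforge@example.org",
           role = c("aut", "cre"))
Description: Implements the sparrow search algorithm (SSA) and a
    multi-strategy improved variant (CGSSA) that combines chaotic-map
    population initialization, chaotic perturbation and Gaussian mutation,
    together with a fourteen-function global-optimization benchmark
    harness. The improved optimizer is used to search the weights of a
    small dense feedforward neural network for binary clinical-outcome
    prediction, evaluated with confusion-matrix metrics, ROC/AUC and
    stratified k-fold cross-validation. A synthetic cohort generator
    emulates the marginal summaries of an esophageal-cancer feature
    schema so the full pipeline is testable without private data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
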