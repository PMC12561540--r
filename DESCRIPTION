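Package: efscontrol
Title: Threshold Parameter Control for Wrapper-Based Evolutionary Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper-based evolutionary feature selection for high-dimensional
    classification with six feature-threshold control mechanisms: a static
    threshold, linear and cosine deterministic schedules, proportional and
    success-rate adaptive feedback controllers, and a self-adaptive
    per-individual threshold gene. Candidate subsets are scored by a k-nearest
    neighbour wrapper fitness combining cross-validated accuracy with a
    subset-size penalty, optimised by self-adaptive differential evolution
    (jDE), classic DE, particle swarm optimisation, or random search. Includes
    a synthetic dataset generator with planted informative, redundant and noise
    features, a replication protocol (stratified splitting, min-max
    normalisation, stratified cross-validation, multi-run experiments,
    generation-to-convergence metric), and Friedman, Nemenyi and Wilcoxon
    signed-rank machinery for ranking methods across datasets.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    class,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
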