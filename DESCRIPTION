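Package: iterscreen
Title: Conformal Prediction and Gain-Cost Optimisation for Iterative
    High-Throughput Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning the second round of an iterative
    high-throughput screening campaign. An initial random screen of a
    compound library is used to train an aggregated, label-conditional
    (Mondrian) conformal classifier built on random-forest vote
    fractions. Internal leave-out validation of the predictor is
    combined with a linear gain-cost function to scan significance
    levels and decide whether to screen the compounds predicted active,
    the whole remaining library, or nothing. Includes a synthetic
    screening-library generator for benchmarking, conformal validity
    and efficiency metrics, and featurisation of SMILES into
    physicochemical descriptors and modulo-folded circular
    fingerprints.
License: MIT
Encoding: UTF-8
Imports:
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
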