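Package: promoterkit
Title: Statistical Profiling, Expression Modelling and Design of Promoter Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synthetic promoter libraries: per-position
    nucleotide statistics (Shannon entropy, consensus, diversity,
    position-expression profiles), one-hot sequence featurization with
    entropy-based position selection, random-forest / gradient-boosted-tree /
    support-vector models of expression strength with replicate-aware
    cross-validation and feature-importance extraction, and genetic-algorithm
    design of new promoter sequences with a desired activity. Includes a
    seeded synthetic-library generator with planted position-nucleotide
    effects for end-to-end validation, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
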