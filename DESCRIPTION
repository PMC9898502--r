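Package: bubblepop
Title: Simulation and Motor-Feature Analysis of a Tablet Bubble-Popping Game
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying visual-motor behaviour measured with a short
    tablet bubble-popping game. Provides a session log data model with JSON
    serialisation and engagement quality control, a configurable synthetic
    game-and-agent simulator (bubble lanes with same-character respawn,
    group- and age-structured touch behaviour, device inertial stream),
    extraction of nineteen families of touch and inertial motor features,
    covariate-adjusted group comparisons (one-way ANCOVA with eta-squared and
    Benjamini-Hochberg false-discovery-rate control, Mann-Whitney tests with
    rank-biserial effect sizes, proportion z-tests, age-adjusted partial
    Spearman correlations), and classifier evaluation via greedy forward
    feature selection maximising leave-one-out cross-validated AUC with
    Hanley-McNeil confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
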