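Package: histoswarm
Title: Swarm Learning Simulation for Weakly Supervised Histopathology
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates decentralized (swarm) training of weakly supervised
    tile-based classifiers for molecular-status prediction from
    histopathology images. Provides a synthetic multi-cohort data
    generator with known ground truth, a slide tessellation and
    edge-based tile quality-control pipeline with Macenko stain
    normalization, pluggable tile feature extraction, a four-layer
    tile-level classifier with patient-level labels and mean score
    aggregation, an in-process multi-peer swarm trainer with basic and
    weighted merge schedules, a replicate evaluation harness
    (patient-level AUROC, t-tests, data-efficiency subsets,
    sync-interval sweeps), and model-examination outputs (prediction
    heatmaps, top-tile export).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    tidyr,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
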