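Package: dalan
Title: Deep Attention-LSTM Aggregation Networks for Patient-Level Image
    Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Patient-level survival modelling from bags of lesion
    region-of-interest (ROI) images. Implements a deep Cox model (DALAN)
    that aggregates a variable number of ROI images per patient through a
    weight-shared convolutional encoder followed by two attention-LSTM
    blocks and a multilayer-perceptron Cox head, together with naive
    ROI-hazard aggregation baselines (average, minimum, maximum, median),
    an image-conditioned survival-time simulator with random censoring,
    and survival evaluation utilities (Cox partial-likelihood loss,
    concordance index, Kaplan-Meier curves, log-rank tests, risk-group
    stratification). The neural layers (convolution, multi-head
    scaled-dot-product attention, stacked LSTM) and the AdamW training
    loop are implemented in base R with exact analytic gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
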