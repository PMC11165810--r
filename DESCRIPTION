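Package: eventlink
Title: Event-Disease Link Prediction on Drug-Target-Disease Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds "event" nodes that collapse drug-target-disease ternary
    relations from pairwise association tables, assembles an event-disease
    heterogeneous graph, and trains a hybrid graph neural network encoder
    (sample-and-aggregate convolution plus typed attention, fused through
    sigmoid gate units and residual connections) with a dot-product decoder
    to predict event-disease links. Includes train/validation/test edge
    splitting with negative sampling, ROC/PR evaluation, an ablation
    harness over encoder and decoder variants, a planted-cluster synthetic
    data generator, and command-line wrappers for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
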