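Package: p300sae
Title: Single-Trial P300 Detection with Stacked Sparse Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and classification pipeline for single-trial detection
    of the P300 event-related potential in oddball-paradigm EEG. Provides a
    synthetic multi-channel EEG session generator with stimulus markers, a
    BrainVision reader, marker-locked epoching, windowed-means feature
    extraction with baseline correction and unit-norm scaling, a from-scratch
    stacked sparse autoencoder (greedy layer-wise pretraining with L2 and
    KL-sparsity regularization, softmax head, supervised fine-tuning), a
    multi-layer perceptron and shrinkage-regularized LDA as baselines, and an
    evaluation layer with accuracy/precision/recall and McNemar paired
    comparisons of classifiers over a multi-subject train/test design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
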