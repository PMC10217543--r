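Package: goafs
Title: Grasshopper Optimization Wrapper Feature Selection for Deep-Feature
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Swarm-intelligence wrapper feature selection for high-dimensional
    real-valued feature tables, such as convolutional-network activations
    extracted from histopathology images. Implements the grasshopper
    optimization algorithm (social-force dynamics with a shrinking comfort
    coefficient), a binary wrapper layer whose fitness combines cross-validated
    classification error with the selected-feature fraction, support-vector
    machine and decision-tree evaluation with the full confusion-matrix panel
    (sensitivity, specificity, accuracy, precision, F1), a seeded synthetic
    generator with planted informative features, feature-table input/output,
    and an end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    rpart,
    stats,
    tools
Suggests:
    EBImage,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
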