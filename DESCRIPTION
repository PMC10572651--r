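Package: fedlung
Title: Simulated Hierarchical Federated Learning for Three-Class Lung
    Nodule Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale simulator of hierarchical federated learning for
    three-way (normal / benign / malignant) lung nodule classification.
    Generates labeled synthetic CT-like slices, extracts physical and
    digital region-of-interest attributes as an eight-dimensional feature
    vector, trains per-client multilayer perceptrons, filters client
    contributions by distributed network thresholding on held-out
    validation scores, aggregates router-wise then centrally by weighted
    parameter averaging, and provides confusion-matrix metrics together
    with centralized-versus-decentralized and node-scaling experiment
    harnesses. Published confusion tables are shipped as fixtures for the
    metric engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
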