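Package: steersim
Title: Virtual Clinical Trial Simulation of Risk-Class Segmentation in
    Low-Dose Tomosynthesis Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation pipeline for assessing whether suspicious findings
    and areas at high risk of masking cancers can be detected in a single
    low-dose breast tomosynthesis projection. Generates cohorts of
    compressed-breast voxel phantoms with Perlin-noise parenchyma and
    embedded soft-tissue lesions, simulates central projections by Siddon
    ray tracing with automatic-exposure-control scaling and Poisson noise,
    derives four-class ground-truth risk maps by label maximum intensity
    projection, trains a convolutional encoder-decoder segmenter with
    weighted cross-entropy, applies post hoc Dirichlet calibration to the
    predicted class probabilities, and evaluates segmentation (pooled ROC,
    Dice, Jaccard, classwise expected calibration error) and lesion
    detection (connected-component findings, FROC) before and after
    calibration.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    graphics,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nnet,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
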