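Package: BrainTumorSeg
Title: Brain Tumor MRI Segmentation and Classification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-stage pipeline for brain tumor detection in 2-D MR
    images: median-filter and high-pass preprocessing, threshold-and-
    morphology skull stripping, fully convolutional pixel classification
    trained with a focal loss, connected-component postprocessing, and
    transfer-learning binary tumor/normal classification with a compact
    inception-style backbone. Includes a seeded synthetic brain-phantom
    generator with pixel-level ground truth, 70/10/20 partitioning,
    record-wise and subject-wise 10-fold cross-validation, and
    confusion-matrix metrics (accuracy, sensitivity, specificity,
    precision, Dice), so the whole pipeline is testable at desk scale
    without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    RNifti,
    png,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
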