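Package: mriseg
Title: Brain MR Slice Classification and Tumor Segmentation by
    Multi-Level Tsallis Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-phase analysis of 2-D T2-weighted brain MR slices. A
    lightweight block-structured convolutional neural network (stem,
    residual identity and projection blocks, inception blocks) classifies
    contrast-enhanced, geometrically augmented slices as normal or
    abnormal; abnormal slices are then segmented by multi-level Tsallis
    entropy thresholding maximized with differential evolution, threshold
    aggregation, binarization and disk-opening morphological refinement.
    Includes a seeded synthetic phantom generator with ground-truth tumor
    masks, stratified cross-validation, confusion-matrix and Dice
    evaluation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
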