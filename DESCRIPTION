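Package: hhocnn
Title: Brain Tumor MRI Classification with a Hawks-Optimized Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for binary brain-tumor classification from
    2-D grayscale MR images: synthetic brain-phantom generation with ground
    truth, median-filter denoising, mean-split sub-histogram equalization,
    fuzzy c-means seeded region growing for candidate tumor segmentation,
    statistical and gray-level co-occurrence texture features, and a small
    convolutional network trained by gradient descent whose output-layer
    weights are refined by a Harris Hawks style population metaheuristic.
    Includes evaluation utilities (confusion matrix, ROC/AUC, Dice) and a
    reproducible command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
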