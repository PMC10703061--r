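Package: rbscreen
Title: Retinoblastoma Fundus-Image Screening with Binary Arithmetic
    Optimization Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational screening pipeline for retinoblastoma-like
    fundus images: specular-spot removal by mask dilation and harmonic
    diffusion inpainting, median smoothing, hue-based multi-level Otsu
    thresholding and K-means colour segmentation, gray-level co-occurrence
    matrix (GLCM) texture features fused with an untrained seeded
    convolutional filter bank, and wrapper feature selection by two binary
    variants of the Arithmetic Optimization Algorithm (BAOA-S and BAOA-V)
    scored by cross-validated k-nearest-neighbour error. Includes seeded
    synthetic fundus-image and feature-table generators with known ground
    truth, the full metric suite (accuracy, precision, sensitivity,
    specificity, F1), ten-fold cross-validation and 70/15/15 splitting,
    and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
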