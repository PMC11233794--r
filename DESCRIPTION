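Package: bcnngrade
Title: Brain Tumor MRI Grading with a Binary Convolutional Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase grading of brain tumors from 2-D grayscale MRI images.
    Phase one standardizes images by nearest-neighbor resizing, denoises them
    with a pixel-wise adaptive Wiener filter, and isolates a candidate tumor
    mask by adaptive local-mean thresholding followed by a morphological
    opening (erosion then dilation with a 22x22 structuring element).  Phase
    two classifies the binary mask into one of five classes (WHO Grade I-IV
    or Healthy) with a small binary convolutional neural network whose
    convolution kernels are quantized to one bit (sign of latent real
    weights, trained with a straight-through estimator).  A synthetic phantom
    generator produces skull-ring/tissue/tumor images with exact ground-truth
    masks so that every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    jpeg,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
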