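Package: svml
Title: Self-Paced SVM Segmentation of Lung MRI with GLGCM Texture Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pixel-wise lung-field segmentation of 2D MRI slices using a
    weighted soft-margin RBF-kernel support vector machine trained under a
    self-paced (easy-samples-first) curriculum. Per-pixel features combine
    quantized intensity and gradient levels with two gray-level gradient
    co-occurrence matrix (GLGCM) statistics computed in a 5x5 window: the
    small-gradient advantage and the inverse difference moment. The package
    also provides segmentation-quality metrics (Dice, sensitivity,
    specificity, mean squared error), quantification of dynamic
    contrast-enhanced time-signal curves (steepest slope, washout ratio,
    curve typing) and apparent diffusion coefficient estimation from
    multi-b-value diffusion-weighted signals, plus a seeded synthetic
    phantom generator that supplies images, ground-truth masks, enhancement
    curves and DWI decays for testing and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
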