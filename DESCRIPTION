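Package: burnscope
Title: Burn-Wound Image Analysis: Color Transformation, Contrast-Kinetic
    Enhancement, Segmentation, Texture Features and Depth Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis toolbox for estimating burn-wound depth and
    per-sample burned-area percentages from RGB photographs. Implements
    perceptual CIE L*u*v* color conversion with Gaussian low-pass filtering,
    a Tofts-model contrast-kinetics simulator driving a luminance enhancement
    operator, two histogram/clustering segmentation algorithms (region-average
    statistics with fuzzy C-means, and a peak-merging reference-region
    labeler), gray-level co-occurrence texture features (contrast and
    correlation for luminance and chroma planes), compact neural classifiers
    (convolutional, feedforward and recurrent) trained with stratified splits
    and image augmentation, and per-sample burned-surface-area reports.
    A seeded synthetic burn-phantom generator provides ground-truth imagery
    so the whole pipeline is testable without clinical photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
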