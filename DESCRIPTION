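Package: earcount
Title: Wheat Ear Counting from In-Field Canopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts wheat ears (spikes) in overhead canopy RGB images. The
    pipeline partitions an image into SLIC superpixels in CIELAB space,
    classifies each candidate region pixel-wise with a VGG-style
    encoder-decoder segmentation network trained on annotated ear/background
    patches, denoises the stitched binary mask with a median filter, separates
    touching ears with a distance-transform watershed, and converts counts to
    ears per square metre using an in-image ground standard of known physical
    size (an A4 sheet). A handcrafted Sobel-edge baseline, count-regression
    evaluation statistics (RMSE, relative RMSE, bias, R squared), a VIA
    annotation reader with augmentation, and a synthetic-canopy generator with
    exact ground truth are included so every stage is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
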