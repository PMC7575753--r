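Package: rodentstrip
Title: Skull Stripping of Rodent Brain MRI with a 2D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automatic skull stripping (brain extraction) for rat and mouse
    MR volumes using a slice-wise 2D U-Net trained with a Dice-coefficient
    loss. Provides NIfTI volume handling with in-plane nearest-neighbor
    resampling and min-max intensity normalization, patch-based training
    with subject-level stratified splits, strided overlapping-tile inference
    with prediction averaging, the standard segmentation evaluation suite
    (Dice, Jaccard, positive predictive value, sensitivity, slice-wise
    in-plane Hausdorff distance), and a synthetic rodent-head phantom
    generator so the full pipeline can be exercised and validated without
    external data. The network forward and backward passes, Dice loss
    gradient, Adam optimizer and gradient-norm clipping are implemented in
    the package with compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    EBImage,
    Rcpp,
    tibble,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
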