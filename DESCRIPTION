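Package: scectgan
Title: Synthetic Contrast-Enhanced CT Generation and Three-Stage Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic contrast-enhanced cardiac CT (SCECT) from
    non-contrast CT (NCT) with a conditional generative adversarial network
    (densely connected encoder-decoder generator against a patch
    discriminator, adversarial plus weighted L1 objective), and validates the
    result in three stages: image quality (MAE, PSNR, SSIM), contour geometry
    (Dice coefficient and mean surface distance with a 5 mm coronary-vessel
    expansion), and dosimetry (DVH metrics: Dmax, Dmean, VxGy). Includes a
    procedural paired-CT phantom simulator with ground-truth cardiac
    substructure masks and a tangential-field dose model, Hounsfield-unit
    preprocessing (resampling, windowing, paired random cropping), NIfTI
    volume I/O, and an end-to-end pipeline with seeded train/validation/test
    splits. The network stack (reverse-mode automatic differentiation,
    convolution kernels, Adam and SGD optimizers) is implemented in R and C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
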