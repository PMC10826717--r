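Package: tieqpi
Title: Single-Shot Quantitative Phase Imaging via the Transport of
    Intensity Equation and a Conditional GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates defocused intensity stacks of phase objects
    (microbeads and unstained-cell phantoms) with an angular-spectrum
    optical forward model, recovers quantitative phase maps with a
    conventional transport-of-intensity (TIE) solver built on an FFT
    Poisson inverse Laplacian, trains a conditional generative
    adversarial network (U-Net generator, PatchGAN discriminator) on
    paired intensity/phase tiles so that a single defocused image yields
    a quantitative phase map, and scores reconstructions with an
    SSIM/MSE/PSNR/UIQI metric suite across defocus planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
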