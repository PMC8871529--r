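Package: tomodose
Title: Simulation and Denoising Study Pipeline for Low-Dose Digital Breast Tomosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation framework for evaluating projection-domain
    denoising in low-dose digital breast tomosynthesis (DBT). Provides a
    voxelized heterogeneous breast phantom with microcalcification and mass
    targets, a limited-angle cone-beam projector with dose-dependent quantum
    and electronic noise, Ram-Lak filtered back projection, two projection
    domain denoisers (a multiscale bilateral filter and a conditional
    adversarial image-to-image network trained with an adversarial plus L1
    objective), an image-quality metric suite (FWHM, CNR, PSNR, SSIM), and
    the statistical comparison layer (Tukey-Kramer all-pairs tests and
    two-way ANOVA) used to compare processing arms across dose levels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    car
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
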