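Package: EchoMap
Title: Ultrasound Echogenicity Map Reconstruction from Speckled B-Mode Images
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation-trained convolutional despeckling for ultrasound
    B-mode imaging. Provides a Rayleigh-speckle forward simulator that turns
    random echogenicity phantoms (cysts, edges, wire targets) into paired
    B-mode/ground-truth training images matched to an estimated point spread
    function (PSF), a residual U-net trained with an L1 + MS-SSIM mixed loss
    implemented with native compute kernels, PSF size estimation from wire
    targets, classical despeckling baselines (non-local means, anisotropic
    diffusion, bilateral), and an image-quality metric suite (CR, CNR, FWHM,
    MSE, PSNR, SSIM, MS-SSIM, mutual information).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    tiff,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'EchoMap-package.R'
    'RcppExports.R'
    'utils.R'
    'baselines.R'
    'phantom.R'
    'simulator.R'
    'dataset.R'
    'io.R'
    'loss.R'
    'methods-show.R'
    'psf.R'
    'metrics.R'
    'unet.R'
    'train.R'
    'pipeline.R'
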