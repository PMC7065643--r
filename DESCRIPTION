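Package: optrecon
Title: Sparse-View Optical Projection Tomography Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of angularly undersampled optical projection
    tomography (OPT) data. Implements a parallel-beam Radon forward model
    with an exactly adjoint backprojector, filtered back projection with a
    frequency-scaled Hann-windowed ramp filter, the TwIST two-step iterative
    shrinkage/thresholding solver for total-variation regularized compressed
    sensing, and a modified U-net convolutional neural network (bilinear
    upsampling, halved expanding-path widths) trained to remove streak
    artifacts from undersampled FBP reconstructions. Includes a synthetic
    sparse-fluorescence phantom generator, a PSNR benchmarking harness
    comparing FBP, compressed sensing and CNN reconstructions, and
    multi-page TIFF volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
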