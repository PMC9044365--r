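Package: mlped
Title: Multi-Level Pooling Encoder-Decoder Networks for Accelerated MRI
    Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and deep-learning reconstruction of accelerated
    multi-coil magnetic resonance acquisitions. Provides a coil-sensitivity
    imaging model with centered orthonormal Fourier transforms, Cartesian
    column under-sampling masks, root-sum-of-squares coil combination, a
    synthetic multi-coil phantom generator, and a multi-level pooling
    encoder-decoder convolutional network (residual multi-kernel pooling,
    zoom-in/zoom-out units, pixel-shuffle upsampling) trained with an L1
    objective and RMSProp, together with NMSE/PSNR/SSIM evaluation and
    fastMRI-dialect HDF5 volume input/output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), rhdf5
SystemRequirements: HDF5 C library
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
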