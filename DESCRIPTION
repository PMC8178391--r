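Package: noise2inverse
Title: Self-Supervised Denoising for Multi-Dimensional Synchrotron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised convolutional denoising of tomographic
    reconstructions without high-quality reference data, following the
    Noise2Inverse principle: the measured sinogram is split into disjoint
    angular (or temporal) sections, complementary sections are reconstructed
    by filtered backprojection, and a compact mixed-scale dense network is
    trained to map one noisy reconstruction to the other.  Supports static
    volumetric data via 2.5D context slices, dynamic acquisitions via
    interlaced angular sampling and combined-time-step targets, and
    multi-channel (diffraction-tomography-like) data via channel-coupled
    angular splits.  Includes a parallel-beam projector/FBP pair, a Poisson
    counting-noise simulator with flat/dark/log correction, synthetic
    phantom generators for all three regimes, a Chambolle-Pock
    total-variation baseline, image quality metrics, and an HDF5/TIFF
    container format with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tiff,
    rhdf5
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
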