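Package: mnf3d
Title: Multifractal Nakagami Features for 3D Ultrasonic Tissue Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric quantitative-ultrasound texture analysis based on the
    multifractal Nakagami feature (MNF) descriptor. Estimates voxel-wise
    Nakagami shape and scale parametric maps from the RF envelope by maximum
    likelihood over cubic voxel lattices, decomposes the parametric volumes
    with an overcomplete (undecimated) octant Daubechies wavelet-packet
    transform, derives voxel-wise fractal-dimension maps from a fractional
    Brownian motion increment model, and assembles an adaptively truncated
    multifractal feature vector for tumor-response classification with a
    Gaussian naive-Bayes classifier and cross-validation. Includes synthetic
    generators (Nakagami speckle, lesion phantoms, fBm volumes, labeled
    cohorts) so the full pipeline runs without external acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    fitdistrplus,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
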