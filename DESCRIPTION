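Package: pasim
Title: Modular Photoacoustic Image Simulation and Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular simulation and image-processing pipeline for
    photoacoustic imaging. Generates voxelized tissue phantoms from
    molecular compositions and geometric structure libraries (including
    random-walk vessel trees and segmentation masks), simulates optical
    fluence with a native 3-D voxel Monte Carlo photon transport solver,
    propagates the resulting initial pressure with a 2-D k-space
    pseudospectral acoustic solver, adds configurable noise, reconstructs
    images with delay-and-sum, delay-multiply-and-sum (signed and
    unsigned) and time-reversal beamforming, and post-processes
    multispectral results with SVD-based linear spectral unmixing and
    iterative fluence-compensated absorption recovery. Pipeline elements
    are exchangeable and persist their results to a hierarchical HDF5
    store; simulated detector data can be exported in an IPASC-style
    HDF5 layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    RNifti,
    knitr,
    rmarkdown
SystemRequirements: HDF5 (libhdf5)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'pasim-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'spectra-library.R'
    'tissue.R'
    'volume.R'
    'devices.R'
    'optical.R'
    'acoustic.R'
    'spectral.R'
    'noise.R'
    'reconstruction.R'
    'store.R'
    'pipeline.R'
    'cli.R'
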