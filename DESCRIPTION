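Package: cereblam
Title: Cerebellar Cortical Laminar Morphometry from Contrast-Enhanced MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-based extraction and morphometry of cerebellar cortical
    laminae from high-resolution contrast-enhanced MRI volumes. Implements a
    Hessian-based planeness filter for the Purkinje layer, Eikonal
    (fast-marching) geodesic fissure skeletonization with resistant layers, a
    Laplace-equation equivolume laminar depth model, Eulerian PDE cortical
    thickness, per-lobule volume/thickness/surface-area/TSR morphometry, and
    W-score (TIV-adjusted) group statistics with FDR and max-T permutation
    correction. Ships an analytic phantom generator (spherical shells, folded
    slabs, simulated cohorts) so every stage is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    scales,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
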