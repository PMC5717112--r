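Package: aortaflow
Title: 4D Flow MRI Haemodynamics of the Ascending Aorta
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for time-resolved three-directional
    phase-contrast MRI (4D flow) of the ascending aorta: velocity
    pre-processing (eddy-current correction, phase unwrapping, noise
    masking), PC-MRA computation and threshold segmentation, peak-systolic
    peak and mean velocity, three-dimensional wall shear stress by the
    inward-normal spline method, viscous energy loss from the dissipation
    function, cohort-averaged shared-geometry maps built by rigid and
    affine mask registration, and per-voxel Mann-Whitney p-value maps with
    significance fractions. Ships an analytic flow-phantom generator
    (Poiseuille, Womersley and eccentric-jet profiles with venc wrapping,
    eddy-current planes and Gaussian noise) that provides closed-form
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
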