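Package: vertrot
Title: Vertebral Axial Rotation Measurement from True-Axial CT Endplate Outlines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the axial rotation of vertebral endplates on
    true-axial computed-tomography slices via a maximum-symmetry-axis search on
    binary endplate masks, and for turning per-endplate angles into
    inter-vertebral (intra-discal) and intra-vertebral rotations, their changes
    between post-operative timepoints, Bland-Altman intra-observer limits of
    agreement used as a significance gate, and cohort-level summaries including
    en-bloc assessment of a fused spinal segment. Includes a synthetic phantom
    generator (endplate outlines, whole spine studies, tilted 3D volumes,
    repeated-observer measurement pairs) with fully known ground truth so every
    stage of the pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    RNifti,
    png,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
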