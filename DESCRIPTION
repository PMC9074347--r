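Package: notchseg
Title: Automatic Femoral Intercondylar Notch Segmentation and Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-wise semantic segmentation of the femoral intercondylar
    fossa (notch) on axial knee MRI with a residual U-Net, physical notch
    volumetry from binary masks (sum of per-slice areas times the slice
    pitch), and the agreement and group-comparison statistics used to
    validate automatic notch measurement: Dice similarity, intraclass
    correlation with F-based confidence intervals, Pearson correlation,
    Bland-Altman limits of agreement, and unpaired two-sample t-tests
    computed from raw values or from printed summary statistics. Includes a
    synthetic knee-notch phantom generator with analytically known notch
    volumes for end-to-end validation, five-fold subject-level
    cross-validation, and NIfTI input/output with voxel geometry handling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
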