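Package: drmap
Title: Voxel-Based Dose-Response Mapping of Organ-at-Risk Surface Dose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for voxel-based dose-response mapping (DRM) of hollow
    organs at risk in radiotherapy. Converts organ contours and 3D dose
    grids into normalized 91x90 dose-surface maps by spherical (bladder)
    or cylindrical (rectum) unwrapping, applies EQD2 fractionation
    correction from the linear-quadratic model, dichotomizes graded
    late-toxicity records with or without baseline correction, and
    performs voxel-wise two-group inference with Welch t-maps,
    Mann-Whitney maps, permutation-based Tmax family-wise error control
    and Dice overlap of significant subregions. Includes a synthetic
    cohort generator (organ geometry, dose field, toxicity outcomes with
    a planted dose-response subregion) so the full pipeline can be
    exercised and validated without access to clinical trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
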