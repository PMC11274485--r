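Package: mamipr
Title: Segmentation-Free PET/CT Outcome Prediction from Multi-Angle
    Maximum Intensity Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for segmentation-free recurrence-free-survival analysis of
    head and neck cancer from paired PET/CT volumes. Provides NIfTI volume
    input/output with isotropic spline resampling, bone-window CT projections
    and anatomical head-and-neck cropping, multi-angle maximum intensity
    projection (MA-MIP) generation, frozen convolutional feature extraction
    with four global pooling operators, six multi-view feature fusion schemes
    (channel-wise statistics, per-channel independent component analysis, and
    an autoencoder), and a repeated nested cross-validated Cox
    proportional-hazards pipeline reporting Harrell's concordance index.
    Includes a synthetic PET/CT phantom and survival-cohort generator so every
    stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    jsonlite,
    xml2,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
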