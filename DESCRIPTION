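Package: maizemold
Title: Mold-Severity Grading of Maize Kernels from Two-Sensor Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for grading mold severity in maize kernels from
    visible/shortwave near-infrared (Vis-SWNIR) and longwave near-infrared
    (LWNIR) hyperspectral images. Covers reflectance calibration against white
    and dark references, mask-based region-of-interest segmentation, mean
    spectrum extraction, per-band gray-level co-occurrence matrix (GLCM)
    texture features, chemometric spectral preprocessing (smoothing,
    multiplicative scatter correction, detrending, centering),
    catalase-activity-based mold-level labeling, VCPA and IRIV wavelength
    selection with a partial least squares discriminant (PLS-DA) fitness,
    pixel-level and feature-level data fusion across sensors, and SVM, random
    forest, and k-nearest-neighbour classification. Includes a synthetic
    hypercube and feature-table generator emulating the statistical structure
    of moldy-kernel imagery, so the full workflow runs and is testable without
    proprietary instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
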