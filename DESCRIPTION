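Package: rootdepth
Title: Inverse Estimation of Tree Effective Rooting Depth from Growth and
    Soil Water Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates species effective rooting depth (ERD) in seasonal
    tropical forests by linking census-interval diameter growth to daily
    soil water potential by depth, vapor pressure deficit, and leaf
    hydraulic vulnerability curves. Provides a calibrated multi-layer
    soil water balance with Latin-Hypercube ensemble calibration,
    day-of-year hydrological drought climatology, leaf vulnerability
    curve fitting and trait-based prediction, forest-census growth
    processing, the depth-wise inverse growth regression with
    isotope-based structure validation, and mortality/exposure
    demography. A seeded synthetic-data generator implements the forward
    version of every model so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
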