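Package: ki67hotspot
Title: Automatic Hot-Spot Selection for Ki-67 Scoring in Brightfield Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates proliferation hot spots in DAB/hematoxylin stained
    whole-slide images and selects fields of quantification for Ki-67
    index scoring. Tissue is masked by opening-based brightness
    equalization, Otsu thresholding and morphological cleanup; hemorrhage
    is removed with a Gaussian-kernel support vector machine over
    sum/difference-histogram (Unser) texture features; immunopositive-cell
    marks are found by extended regional minima of the CIE Luv u channel;
    fields are chosen greedily under a spatial dispersion penalty. Also
    provides observer-concordance statistics (a localization concordance
    measure, Kendall's tau-b with bootstrap confidence intervals) and a
    seed-reproducible synthetic slide generator with ground truth for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    grDevices,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
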