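Package: cfuseg
Title: Seeded Segmentation and Enumeration of Colony Forming Units
Version: 0.1.0
Authors@R:
    person("cfuseg", "maintainers", email = "cfuseg@example.org", role = c("aut", "cre"))
Description: Counts bacterial colony forming units (CFU) on backlit petri-dish
    photographs. From one user-clicked representative colony per color class,
    the pipeline measures a priori colony attributes, searches local adaptive
    threshold parameters whose binarization satisfies grayscale-histogram
    validity criteria, identifies single colonies by DBSCAN clustering of
    contour shape and color features, splits merged colonies by watershed
    flooding seeded at prominence-filtered local gray-level minima, and reports
    counts grouped by colony color. Includes a seeded synthetic plate-image
    generator with ground-truth annotations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
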