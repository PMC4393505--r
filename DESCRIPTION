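Package: mammocad
Title: Associative Rule-Based Computer-Aided Diagnosis for Mammograms
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A local, testable implementation of an associative-classification
    pipeline for medio-lateral oblique (MLO) mammograms: breast-contour
    identification and pectoral-muscle removal (region-based level set plus
    seeded region growing), orthogonal-polynomial edge detection with
    distance-regularized level-set refinement, a fixed-layout 1037-dimensional
    four-family texture feature extractor, inconsistency-driven joint feature
    selection and discretization, class-constrained representative
    association-rule mining over an FP-tree, and an associative diagnosis
    engine that returns weighted diagnosis keyword sets under two matching
    conditions.  A phantom module generates synthetic mammograms with ground
    truth and labeled transaction cohorts with planted rules so every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
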