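Package: mammotrace
Title: Semi-Automated Breast Lesion Annotation for Digital Mammography and Tomosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for semi-automated annotation of breast lesions
    on digital mammography (DM) and digital breast tomosynthesis (DBT) images.
    Provides intelligent-scissors (live-wire) contour tracing between user
    waypoints via Dijkstra shortest paths on an image cost graph, a
    non-destructive annotation data model with BI-RADS morphology descriptors,
    lesion size measurement (Feret diameter, cross-section area), mask/CSV/text
    export for radiomics pipelines, a minimal DICOM reader/writer, and a
    synthetic phantom generator producing DM/DBT cases with known ground-truth
    contours for fully reproducible end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
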