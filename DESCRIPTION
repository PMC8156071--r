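Package: lymphopatch
Title: Patch-Based Deep Learning Classification of Nodal Lymphoma with
    Quality-Controlled Case Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale implementation of a
    histopathological lymphoma-classification workflow: extraction of
    fixed-physical-size image patches (100 x 100 micrometres) from
    polygon-annotated H&E tissue images, patient-level train/validation/test
    splitting with leak checking, training and selection of a
    compound-scaled convolutional patch classifier, aggregation of
    patch-level class probabilities to case-level diagnoses by majority
    vote with two-level quality control (patch-level PQC and case-level
    CQC abstention thresholds), balanced-accuracy evaluation with an
    aggregated tumor-free reference class, and SmoothGrad saliency maps.
    A synthetic lymph-node image generator with ground-truth annotations
    and controllable prediction fixtures makes every stage testable
    without external data or a GPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    jsonlite,
    yaml,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
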