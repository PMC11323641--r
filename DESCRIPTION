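Package: astromorph
Title: Morphometric Classification of Reactive Astrocytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-cell morphometrics and morphology-based classification of
    reactive astrocytes after traumatic brain injury. Computes ten 2D/3D
    size- and shape-related parameters (area, convex hull area, perimeter,
    circularity, solidity, total process length, primary and secondary branch
    counts, thickness, and Sholl intersections/radius) from SWC skeleton
    traces and binary cell masks; screens variability with coefficient-of-
    variation bands; delineates the contusion core from pericontusional
    tissue on GFAP intensity profiles; selects clustering features with a
    Sarle-type multimodal index; clusters cells by hierarchical clustering,
    PCA and t-SNE plus HDBSCAN; builds a confidence-interval logical tree of
    reactive-response intensity categories; and analyses clonal composition
    from multicolor fluorophore barcodes. A synthetic-data generator emulates
    the study design so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Rtsne,
    jsonlite,
    digest
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
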