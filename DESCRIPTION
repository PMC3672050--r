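Package: gapwave
Title: Cell-Type Transcript Dynamics in the Irradiated Mouse Testis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for whole-testis expression time courses during
    recovery from low dose irradiation, where the loss and re-population of
    germ-cell stages moves a "gap" through the seminiferous epithelium and
    changes in cellularity drive apparent expression changes. Implements a
    smoothness-based enrichment score with a permutation false discovery rate
    and a probe-level dispersion filter to select transcripts tracking
    cellularity, correlation-distance partitioning-around-medoids clustering
    with automatic choice of the number of clusters, marker-based assignment
    of clusters to testicular cell populations, hypergeometric
    over-representation analysis against gene-set collections, and
    quantification of Leydig-cell staining area from section images. A seeded
    synthetic-data module generates probe-level expression matrices and
    stained-section images with known ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    limma,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
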