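Package: serocell
Title: Single-Cell RNA-Seq Analysis of Serous Ovarian Tumor Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for droplet single-cell RNA-seq
    of serous epithelial ovarian tumors: knee-plot cell calling from barcode
    UMI totals, quality-control filtering, log-normalization, cell-cycle
    scoring and covariate regression, variable-gene selection, PCA with
    automatic elbow selection, shared-nearest-neighbor graph clustering,
    marker-panel cluster annotation, zero-inflated negative-binomial
    likelihood-ratio differential expression with biomarker thresholds,
    per-sample cell-composition analysis with Fisher enrichment, and
    TCGA-subtype signature scoring and classification. Includes a seeded
    zero-inflated negative-binomial cohort simulator so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    ape,
    Rtsne,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
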