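Package: brainpls
Title: Imaging Transcriptomics of Regional Brain Change with Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links regional gene expression to maps of longitudinal gray-matter
    volume change with partial least squares (PLS) regression. Builds
    region-by-gene expression matrices from multi-donor microarray tables
    (probe annotation and intensity filtering, differential-stability probe
    selection, sample-to-parcel assignment, scaled robust sigmoid
    normalization), computes TIV-adjusted regional change t-maps, assesses
    the PLS association with a spherical-rotation (spin) spatial permutation
    null and bootstrap gene Z-scores with FDR control, predicts symptom
    change from regional volume change with a subject-level PLS, and tests
    PLS-derived gene lists for cell-type enrichment by hypergeometric
    over-representation and permutation GSEA. Includes a synthetic-data
    generator with planted ground truth for end-to-end recovery and
    calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
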