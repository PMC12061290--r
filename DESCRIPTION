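Package: imtkit
Title: Combinatorial scATAC Preprocessing and Time-Course Fate Dynamics
    for Multi-Lineage Trans-Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for the bespoke computational stages of a chemically
    induced multi-lineage trans-differentiation (iMT) single-cell study.
    Covers preprocessing for a combinatorial-barcode Microwell scATAC assay
    (split-pool barcode extraction, quality gating, one-mismatch whitelist
    correction, 28-bp trimming, Tn5 +4/-5 insertion-site shift, per-cell
    fragment files and TSS-enrichment quality control), scRNA count-matrix
    processing (ln(CPM/100+1) normalization, highly variable gene selection,
    control-binned gene-set scores, gene-pair co-expression scores), a
    correlation-based network-entropy potency surrogate (CCAT) with
    cross-species homology weighting, pseudo-cell neighbor-voting AUROC
    cell-type matching, and time-course fate mapping by unbalanced entropic
    optimal transport (ancestor pull-back, membership thresholding, ancestor
    divergence, gene trends, driver-gene correlation). A seeded synthetic-data
    generator emulates every input with ground-truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    Rsamtools,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
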