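Package: spotscore
Title: Spot-Level Gene-Set Scoring for Visium Spatial Transcriptomics of
    Inflamed Skin
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying type I interferon-driven inflammation in
    10x Visium spatial transcriptomics of skin biopsies.  Reads Space
    Ranger-style sample directories, applies detected-gene spot quality
    control, and computes spot-level gene-set positivity statistics:
    interferon-stimulated-gene (ISG) panel fractions stratified by skin
    compartment, macrophage M1/M2 polarization within CD68-positive spots,
    apoptosis/necroptosis marker co-occurrence, hypergeometric multimodal
    intersection analysis (MIA) against a single-cell reference,
    non-negative least-squares signature deconvolution with threshold
    summaries, Wilcoxon rank-sum marker detection with min-pct and
    log-fold-change filters, and group comparisons by two-tailed t or
    permutation tests.  Also quantifies companion in vitro readouts
    (delta-delta-Ct relative expression; cell-area thresholding of labelled
    segmentation masks) and ships a seeded synthetic-data generator with
    recorded ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    pracma,
    yaml,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
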