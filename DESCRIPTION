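Package: comethnet
Title: Co-Methylation Network Modules, Cell-Type Enrichment and Refined
    Polygenic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale pipeline linking DNA co-methylation network modules
    in brain tissue to neuropsychiatric traits. Builds unsigned weighted
    co-methylation networks from array beta values (soft thresholding,
    topological overlap, module detection, module eigengenes), correlates
    module eigengenes with clinical traits under per-region Bonferroni
    control, tests module gene sets for cell-type enrichment against
    single-nucleus expression references with a bootstrap specificity test
    (including conditional analysis), and refines clumping+thresholding
    polygenic risk scores to genomic windows around module CpG sites, with
    time-dependent Cox and Kaplan-Meier modelling of conversion to
    depression. Includes a synthetic-data module with planted ground truth
    that emulates every input the analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    Matrix,
    jsonlite,
    survival,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
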