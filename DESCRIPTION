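Package: rrbspipe
Title: Simulation and Differential Methylation Analysis for Reduced
    Representation Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing reduced representation bisulfite
    sequencing (RRBS) methylation count data: replicate pooling, coverage
    gating, per-CpG methylation levels, Spearman sample correlation,
    level-category summaries, Fisher's-exact differential methylation
    calling with a strong-effect threshold, DMC-to-DMR chaining and
    cross-comparison DMR merging, promoter CpG-density classification
    (HCP/ICP/LCP), genomic-location and imprinted-region annotation, and
    K-means/hierarchical clustering with expression Z-score integration.
    Includes a seeded synthetic RRBS generator (toy genome with feature
    catalogue, cell-type-specific Beta-mixture methylation states,
    in-silico MspI digestion with fragment size selection, and
    bisulfite-converted count simulation) so that every analysis stage is
    exercisable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
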