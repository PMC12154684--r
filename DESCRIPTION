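Package: subtercap
Title: Analysis of Great Ape Subterminal Heterochromatic Caps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the subterminal heterochromatic caps of
    African great ape chromosomes: decomposition of cap sequences into
    pCht satellite units, variant typing and higher-order block
    classification by two-step k-means; composition-based hierarchical
    clustering of caps with bootstrap support; distance-based phylogenetics
    of segmental-duplication spacers with molecular-clock calibration;
    anchor-based detection of ectopic (non-allelic) exchanges with
    breakpoint refinement; resampling tests for breakpoint-spacer
    proximity, phylogenetic topology shifts, group identity differences
    and boundary feature enrichment; and euchromatin-boundary profiling of
    insertions and CpG methylation. A synthetic-cap simulator with planted
    truth makes every stage testable without external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    cluster,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
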