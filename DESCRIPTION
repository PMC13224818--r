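Package: nodufam
Title: Gene Duplication and Tissue Expression Bias in Nodulation Gene Superfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for superfamily-level analysis of gene duplication and
    tissue-expression bias in root-nodule-symbiosis gene families. Enumerates
    legume gene clades from the leaf listing of rooted gene trees (strict and
    single-intruder-permissive modes), classifies same-species paralog pairs by
    genomic proximity into tandem, proximal and distal relations, infers
    segmental (whole-genome duplication) versus local origin for duplicated
    clades, detects ancient retained local duplications, assigns two-fold
    tissue-bias labels (nodule, root, shoot, neutral) at gene and superfamily
    level with cross-species conservation categories, and compares per-species
    family-size distributions with the Kruskal-Wallis test, epsilon-squared
    effect size and pairwise Wilcoxon rank-sum tests under Benjamini-Hochberg
    correction. A bundled gene-family evolution simulator with event logging
    provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
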