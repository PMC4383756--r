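Package: dclineage
Title: Cross-Platform Transcriptomic Lineage Classification of Dendritic
    Cell Subsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which immune lineage a sorted blood cell
    population belongs to when its transcriptome was measured on one
    platform (RNA-seq) and the reference lineage panel on another
    (microarray). Implements probe-region-restricted RPKM quantification
    of read alignments, rank-invariant cross-platform normalization,
    fold-change and empirical-Bayes moderated-t differential expression
    with Benjamini-Hochberg adjustment, a directional concordance
    statistic that scores query-derived gene sets against a reference
    lineage contrast, and complete-linkage hierarchical clustering plus
    principal component analysis for lineage assignment. Ships a
    synthetic two-platform data generator with planted lineage structure,
    differential-expression sets and concordance fractions, so the whole
    pipeline can be validated end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    withr
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
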