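Package: regcouple
Title: Molecular Determinants of Expression Coupling Between Transcription
    Factors and Their Target Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to ask which molecular features separate
    expression-correlated from uncorrelated transcription-factor/target-gene
    (TF-TG) regulatory pairs. Builds candidate pairs by scanning gene
    promoters with position weight matrices at a relative-score threshold,
    computes pairwise Pearson expression correlation, selects "active" TFs
    against a resampling null, assembles a multi-category feature panel
    (motif information content and composition, TFBS-TSS distances,
    regulatory- and protein-interaction-network measures, transcript and
    protein annotation, methylation and open-chromatin tracks, adjacent-gene
    context), screens features univariately (Wilcoxon, Cohen's D, BH FDR,
    Fisher enrichment), and trains a Random Forest under component-disjoint
    cross-validation with permutation importance and conditional-depth
    feature-interaction analysis. A fully parameterized synthetic-data
    generator with a ground-truth manifest makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    limma,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
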