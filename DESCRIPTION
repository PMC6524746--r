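Package: ecdtu
Title: Differential Transcript Usage from Equivalence Class Counts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects differential transcript usage (DTU) between conditions
    by statistical testing of RNA-seq equivalence class counts (ECCs), the
    per-sample read counts of transcript compatibility classes produced by
    lightweight aligners. Parses Salmon and kallisto equivalence-class
    output, matches classes across samples into a gene-annotated count
    matrix, and tests each gene for differential usage with a negative
    binomial GLM likelihood-ratio test on feature counts, aggregating
    feature p-values into gene-level q-values. Also provides the two
    comparator quantifications (EM transcript abundance estimation from
    equivalence classes, and flattened disjoint exon-bin counting), a
    built-in k-mer pseudo-aligner, a ground-truth isoform-switch
    simulator, and evaluation utilities (TPR/FDR at nominal cutoffs,
    consensus truth sets, subset experiments, counting-bin and
    variance-to-mean diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
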