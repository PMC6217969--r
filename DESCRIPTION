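Package: pathconverge
Title: Convergence of Transcriptomic and GWAS Gene-Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for detecting pathway-level convergence between
    differential gene-set enrichment in expression studies and gene-set
    enrichment of GWAS variant associations. Implements a weighted
    Kolmogorov-Smirnov running-sum enrichment score with phenotype and
    gene-set permutation nulls, normalized enrichment scores, permutation
    FDR and leading-edge extraction; a MAGENTA-style GWAS arm with windowed
    SNP-to-gene assignment, best-SNP gene scores, regression-based confounder
    correction and percentile-cutoff enrichment; and the bidirectional
    custom-superset cross-interrogation that intersects leading-edge genes
    across the two arms. A synthetic-data module generates expression
    studies, gene-set collections, gene annotations and GWAS summary
    statistics with planted, recorded ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
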