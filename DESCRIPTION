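Package: ricepop
Title: Population Genomics of Structured, Inbred Rice Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for resequencing-based population genomics of highly
    inbred, structured crop diversity panels, built around a rice
    (Oryza sativa) landrace workflow. Provides an inbreeding-aware SNP
    filtering cascade (hard filters, a Hardy-Weinberg heterozygosity-excess
    filter calibrated by Wright's inbreeding coefficient F, LD pruning and
    distance thinning), maximum-likelihood admixture inference by EM with
    replicate-run alignment and Evanno delta-K model selection,
    threshold-based subpopulation assignment, PCA and principal-coordinate
    embeddings, sliding-window nucleotide diversity (pi), mixed-linear-model
    GWAS with a genomic kinship random effect and ancestry covariates, and
    rule-based aggregation of significant associations into QTL regions with
    gene overlap counts. A synthetic-population simulator (Balding-Nichols
    divergence, Dirichlet admixture, genotype-level inbreeding, additive
    traits) makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
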