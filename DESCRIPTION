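Package: twaspipe
Title: Multi-Locus Transcriptome-Wide Association Screening for Carcass Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a candidate-gene discovery
    pipeline for quantitative carcass traits from bulk RNA-seq and whole-genome
    genotypes. The core is a multi-locus elastic-net association model tuned by
    the one-standard-error cross-validation rule, combined with a weighted gene
    co-expression network stage (soft threshold, topological overlap, module
    eigengenes, hub screening), extreme-group differential expression, a
    three-way candidate intersection, and mixed-linear-model expression GWAS
    with per-SNP association tests. A synthetic-data generator with planted
    ground truth (negative-binomial counts, latent-factor gene modules,
    cis-eQTLs, traits built from causal gene expression) supports type-I-error
    and power simulation studies and end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    DESeq2,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
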