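Package: scDivergence
Title: Genotype-Driven Developmental Divergence in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify developmental divergence between two genotypes
    (for example an isogenic euploid/trisomic pair) from single-cell RNA-seq
    counts. Implements quality control and log-normalization, highly variable
    gene selection, PCA, 2D embedding and graph clustering, expression-based
    aneuploidy dosage detection from binned genomic coverage and pseudobulk
    differential expression, per-cluster binomial detection-rate tests,
    diffusion-map embedding with automatic kernel width selection, flood
    pseudotime from root cells, a permutation-based inter-genotype distance
    (IGD) statistic on diffusion components, Moran's I gene-graph association,
    and hypergeometric gene-list overlap statistics. A seeded synthetic data
    generator produces two-genotype counts with known dosage, cluster and
    trajectory-divergence structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    uwot,
    RANN,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
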