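Package: screqtl
Title: Single-Cell RNA Quantitative Trait Loci from Variant Allele Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlates per-cell variant allele fraction (VAF_RNA) at expressed
    biallelic SNV loci with gene expression across single cells, stratified by
    donor and cell type. Implements the full scReQTL workflow: cell quality
    control, expression normalization, variable-gene selection,
    principal-component covariates, pooled biallelic locus selection,
    coverage (minR) masking, variability filtering with a binomial
    chance-variability computation, per-pair linear models with
    Benjamini-Hochberg FDR control, gene-residence cis/trans annotation, and
    permutation-based enrichment of gene pairs in known interaction sets.
    Includes a synthetic-data generator with planted effects so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
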