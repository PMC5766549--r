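Package: milknet
Title: Mixed-Model GWAS and Co-Association Network Inference for Milk
    Protein Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for the genetic dissection of correlated
    dairy traits such as milk nitrogen fractions. Implements marker quality
    control, an identity-by-state genomic relationship matrix, fast
    single-component REML for genomic heritability, the GRAMMAR residual
    association scan with gamma recalibration and genomic control,
    conditional scans on lead variants, SNP-to-gene mapping with Fisher
    gene-set over-representation tests, construction of an association
    weight matrix (AWM) around a key phenotype, a permutation test for the
    phenotypic variance captured by the selected markers, and PCIT
    partial-correlation network inference with topology summaries,
    transcription-factor trio selection and activator/repressor
    classification. A seeded synthetic-cohort generator emulating a dairy
    cohort design makes every stage testable without external data.
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
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
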