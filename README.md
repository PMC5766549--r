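# milknet

Integrated genetic analysis of correlated dairy traits — mixed-model GWAS
with genomic control, genomic heritability, gene-set over-representation,
association-weight-matrix (AWM) construction and PCIT co-association network
inference — packaged for R with a seeded synthetic-cohort generator so that
every stage is testable end to end without access to proprietary cow data.

## Who this is for

Quantitative geneticists and systems biologists working on milk-composition
traits (casein and whey fractions, urea, total protein nitrogen) or any
similarly structured panel of correlated phenotypes measured on a
herd-structured cohort with dense SNP genotypes. The package covers the full
path from PLINK files to a transcription-factor-annotated gene network.

## The models at the core

**Polygenic mixed model.** For each trait,
`y = Xβ + a + e`, with `a ~ N(0, K σ_g²)` and `e ~ N(0, I σ_e²)`, where `K`
is a marker-based relationship matrix. The identity-by-state coefficients
are

    f_ij = (1/N) Σ_k (x_ik − p_k)(x_jk − p_k) / (p_k (1 − p_k)),

with genotypes coded 0, ½, 1 and `p_k` the "+"-allele frequency; for the
mixed model the matrix is rescaled to unit mean diagonal so that genomic
heritability is the variance fraction `h² = σ_g²/(σ_g² + σ_e²)`. REML uses
the spectral decomposition of `K` and a one-dimensional profile search over
`h²`.

**GRAMMAR-GC association scan.** BLUP residuals from the polygenic fit are
regressed on each SNP; a gamma recalibration undoes the residual-regression
deflation of effect sizes and test statistics, and genomic control
(`λ = median(χ²)/0.4549`) corrects remaining miscalibration. Per-SNP
variance is `2pqa²`, reported as a percentage of `σ_g²`. A conditional scan
refits with lead SNPs as fixed covariates.

**AWM–PCIT network.** SNPs associated with a key phenotype (`P ≤ 0.05`) or
with ≥ 3 other traits (`P < 0.05`), and lying < 10 kb from their nearest
gene, form a genes × traits matrix of standardized effects (one SNP per
gene). Pearson correlations between gene rows feed the PCIT algorithm,
which removes edges explained by an indirect path through any third gene
(first-order partial correlations with a trio-wise tolerance); edges with
`|r| ≥ 0.80` form the network. Exhaustive search over transcription-factor
triples finds the trio whose direct neighborhoods cover the most genes, and
edge signs classify targets as induced or repressed.

## Worked example

```r
library(milknet)

dir <- tempfile("demo")
manifest <- run_pipeline(demo_pipeline_config(dir, seed = 1))

str(manifest[c("n_snps_post_qc", "n_significant", "awm_genes",
               "network_edges")])
#> List of 4
#>  $ n_snps_post_qc: int 3000
#>  $ n_significant : int 5
#>  $ awm_genes     : int 128
#>  $ network_edges : int 1668

jsonlite::read_json(file.path(dir, "permutation.json"))[
  c("observed_var_fraction", "null_mean", "empirical_p")]
#> $observed_var_fraction
#> [1] 0.6497490
#> $null_mean
#> [1] 0.04745197
#> $empirical_p
#> [1] 0.001996008
```

The demo simulates 300 cows genotyped at 3,000 SNPs with six correlated
traits and a major QTL contributing half the additive variance of the key
trait. All 3,000 simulated markers pass QC (the generator draws common,
well-behaved SNPs); five SNPs pass the genome-wide threshold
(P < 5 × 10⁻⁵); the AWM retains 128 genes whose markers explain ~65% of the
key trait's phenotypic variance versus ~4.7% for random SNP sets of the
same size (permutation P ≈ 0.002) — the co-association signal the network
stage then decomposes into 1,668 PCIT edges, node centralities and a best
TF trio (`tf_trio.json`, `node_metrics.tsv`, `network.sif`).

Individual stages are plain functions returning tibbles, so the pipeline
can be driven piecewise:

```r
co  <- simulate_cohort(sim_config(n_individuals = 300, n_snps = 2000, seed = 1))
qc  <- apply_qc(co$genotypes)
grm <- build_grm(qc$genotypes)
assoc <- gwas_scan(co$phenotypes, qc$genotypes, grm)
autoplot(assoc)                      # Manhattan plot per trait
awm <- build_awm(assoc, co$annotation$genes, key_trait = "trait_1")
net <- filter_edges(pairwise_correlation(awm), pcit(pairwise_correlation(awm)),
                    tf_catalog = co$annotation$tf_catalog)
best_tf_trio(net)
```

A thin command-line wrapper is installed at `inst/cli/milknet`
(`milknet simulate|run --config config.yaml`).

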