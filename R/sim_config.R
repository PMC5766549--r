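#' Simulation configuration for a synthetic dairy cohort
#'
#' Describes the cohort design the generator emulates: a herd-structured set
#' of cows with parity and days-in-milk (DIM) class effects, a dense biallelic
#' SNP panel across autosomes, a battery of correlated milk-composition traits
#' organised in correlation clusters, per-trait narrow-sense heritabilities,
#' and optional major QTL that absorb a stated fraction of the additive
#' variance of one or more traits.
#'
#' Defaults mirror a downscaled version of the emulated study design
#' (1,011 cows, 37,568 SNPs on 29 autosomes, 15 traits in three correlation
#' clusters, 85 herd-test-date groups, parity classes 1/2/3/4+, 30-day DIM
#' classes, per-trait h2 spanning roughly 0.1-0.8, and a casein-cluster-like
#' major QTL explaining up to ~70% of additive variance for the key trait).
#'
#' @param n_individuals Number of cows.
#' @param n_snps Number of biallelic SNPs.
#' @param n_chromosomes Number of autosomes the panel is spread over.
#' @param maf_range Length-2 numeric in (0, 0.5]: allele-frequency range the
#'   per-SNP "+"-allele frequency is drawn from (uniform).
#' @param n_traits Number of phenotypes.
#' @param trait_clusters Integer vector of length `n_traits` assigning each
#'   trait to a residual-correlation cluster.
#' @param within_cluster_corr Residual correlation between traits sharing a
#'   cluster, in `[0, 1)`.
#' @param h2 Numeric vector of length `n_traits` of narrow-sense
#'   heritabilities in `[0, 0.99]`.
#' @param qtl List of QTL specs, each a list with elements `chr`, `snp_index`
#'   (index of the marker on that chromosome tagging the QTL), `traits`
#'   (integer indices of affected traits) and `var_frac` (fraction of the
#'   trait's additive variance in `(0, 1)` assigned to the QTL).
#' @param n_herds Number of herd-date contemporary groups.
#' @param parity_classes Number of parity classes.
#' @param dim_classes Number of 30-day days-in-milk classes.
#' @param ld_decay Haplotype copy probability in `[0, 1)` between adjacent
#'   SNPs; 0 gives linkage equilibrium, values near 1 give long LD blocks.
#' @param n_sires Number of paternal half-sib families: each cow receives one
#'   recombined haplotype from a randomly assigned sire and one
#'   population-drawn dam haplotype, reproducing the relatedness structure of
#'   an artificial-insemination dairy cohort (which is what makes GRM-based
#'   variance components estimable). Set to 0 for fully unrelated
#'   individuals.
#' @param recomb_rate Per-interval switch probability between the two sire
#'   haplotypes when forming the paternal gamete.
#' @param herd_sd,parity_sd,dim_sd Standard deviations of the normal class
#'   effects (phenotypic-SD units).
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_individuals = 1011,
                       n_snps = 37568,
                       n_chromosomes = 29,
                       maf_range = c(0.05, 0.5),
                       n_traits = 15,
                       trait_clusters = rep(1:3, length.out = n_traits),
                       within_cluster_corr = 0.6,
                       h2 = seq(0.1, 0.8, length.out = n_traits),
                       qtl = list(),
                       n_herds = 85,
                       parity_classes = 4,
                       dim_classes = 10,
                       ld_decay = 0,
                       n_sires = 40,
                       recomb_rate = 0.02,
                       herd_sd = 0.5,
                       parity_sd = 0.3,
                       dim_sd = 0.3,
                       seed = 1L) {
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  if (n_individuals < 2 || n_snps < 1) {
    abort("Need at least 2 individuals and 1 SNP.")
  }
  if (length(h2) != n_traits) abort("`h2` must have one value per trait.")
  if (any(h2 < 0) || any(h2 > 0.99)) abort("`h2` values must lie in [0, 0.99].")
  if (length(trait_clusters) != n_traits) {
    abort("`trait_clusters` must assign every trait to a cluster.")
  }
  if (within_cluster_corr < 0 || within_cluster_corr >= 1) {
    abort("`within_cluster_corr` must lie in [0, 1).")
  }
  if (ld_decay < 0 || ld_decay >= 1) abort("`ld_decay` must lie in [0, 1).")
  if (n_sires < 0) abort("`n_sires` must be non-negative.")
  if (recomb_rate < 0 || recomb_rate > 0.5) {
    abort("`recomb_rate` must lie in [0, 0.5].")
  }
  for (q in qtl) {
    if (is.null(q$var_frac) || q$var_frac <= 0 || q$var_frac >= 1) {
      abort("QTL `var_frac` must lie in (0, 1).")
    }
    if (is.null(q$chr) || is.null(q$snp_index) || is.null(q$traits)) {
      abort("Each QTL needs `chr`, `snp_index` and `traits`.")
    }
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_snps = as.integer(n_snps),
      n_chromosomes = as.integer(n_chromosomes),
      maf_range = as.numeric(maf_range),
      n_traits = as.integer(n_traits),
      trait_clusters = as.integer(trait_clusters),
      within_cluster_corr = within_cluster_corr,
      h2 = as.numeric(h2),
      qtl = qtl,
      n_herds = as.integer(n_herds),
      parity_classes = as.integer(parity_classes),
      dim_classes = as.integer(dim_classes),
      ld_decay = ld_decay,
      n_sires = as.integer(n_sires),
      recomb_rate = recomb_rate,
      herd_sd = herd_sd,
      parity_sd = parity_sd,
      dim_sd = dim_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d cows, %d SNPs / %d chr, %d traits, %d QTL, seed %d\n",
    x$n_individuals, x$n_snps, x$n_chromosomes, x$n_traits,
    length(x$qtl), x$seed
  ))
  invisible(x)
}
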