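#' Marker quality-control thresholds
#'
#' @param min_call_rate Minimum per-SNP call rate; markers are retained when
#'   call rate is strictly greater.
#' @param min_maf Minimum minor allele frequency (strictly greater retained).
#' @param hwe_alpha Hardy-Weinberg exact-test significance level; markers are
#'   retained when the exact P exceeds the (possibly Bonferroni-divided)
#'   level.
#' @param hwe_bonferroni Divide `hwe_alpha` by the number of tested markers?
#' @param hwe_m Number of tests used for the Bonferroni division; `NULL`
#'   (default) uses the pre-filter marker count of the input.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.005,
                          hwe_alpha = 0.001, hwe_bonferroni = TRUE,
                          hwe_m = NULL) {
  for (v in c(min_call_rate, min_maf, hwe_alpha)) {
    if (v <= 0 || v >= 1) abort("QC thresholds must lie in (0, 1).")
  }
  structure(
    list(min_call_rate = min_call_rate, min_maf = min_maf,
         hwe_alpha = hwe_alpha, hwe_bonferroni = isTRUE(hwe_bonferroni),
         hwe_m = hwe_m),
    class = "qc_thresholds"
  )
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on genotype counts (Wigginton, Cutler & Abecasis
#' 2005): the P-value is the total probability, under the conditional
#' distribution of heterozygote counts given allele counts, of outcomes no
#' more probable than the observed one. Mid-P is not applied.
#'
#' @param n_het Number of heterozygotes.
#' @param n_hom1,n_hom2 Numbers of the two homozygote classes.
#' @return Exact two-sided P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalised probabilities by recurrence from the smallest het count
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i]
    # P(h) / P(h-2) = 4 * n_r(h-2) * n_c(h-2) / (h * (h-1))
    hr_prev <- (n_rare - hets[i - 1]) / 2
    hc_prev <- n - hets[i - 1] - hr_prev
    logp[i] <- logp[i - 1] + log(4 * hr_prev * hc_prev) - log(h * (h - 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Apply marker quality control
#'
#' Retains SNPs with call rate above `min_call_rate`, minor allele frequency
#' above `min_maf` (computed from non-missing calls only) and exact
#' Hardy-Weinberg P above `hwe_alpha` (divided by the marker count when
#' `hwe_bonferroni` is set). Each removed SNP is tagged with the first
#' failing criterion in the order call rate, MAF, HWE.
#'
#' @param g A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (tibble: `snp`, `call_rate`, `maf`, `hwe_p`, `retained`, `reason`).
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  if (ncol(g$dosage) == 0) abort("Empty genotype matrix.")
  fr <- snp_freq(g)
  m <- ncol(g$dosage)
  hwe_p <- vapply(seq_len(m), function(j) {
    x <- g$dosage[, j]
    hwe_exact_test(sum(x == 1, na.rm = TRUE), sum(x == 2, na.rm = TRUE),
                   sum(x == 0, na.rm = TRUE))
  }, numeric(1))
  hwe_m <- if (is.null(thresholds$hwe_m)) m else thresholds$hwe_m
  hwe_cut <- if (thresholds$hwe_bonferroni) thresholds$hwe_alpha / hwe_m else thresholds$hwe_alpha
  fail_cr <- !(fr$call_rate > thresholds$min_call_rate)
  fail_maf <- !(fr$maf > thresholds$min_maf)
  fail_hwe <- !(hwe_p > hwe_cut)
  retained <- !(fail_cr | fail_maf | fail_hwe)
  reason <- rep(NA_character_, m)
  reason[fail_hwe] <- "hwe"
  reason[fail_maf] <- "maf"
  reason[fail_cr] <- "call_rate"
  report <- tibble::tibble(
    snp = fr$snp, call_rate = fr$call_rate, maf = fr$maf, hwe_p = hwe_p,
    retained = retained, reason = reason
  )
  if (!any(retained)) {
    warn("Quality control removed every SNP; returning an empty genotype matrix.")
  }
  list(
    genotypes = subset_genotypes(g, snps = which(retained)),
    report = report
  )
}
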