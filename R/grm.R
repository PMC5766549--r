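#' Identity-by-state genomic relationship matrix
#'
#' For individuals i and j, the relationship coefficient is
#' \deqn{f_{ij} = \frac{1}{N}\sum_k \frac{(x_{ik}-p_k)(x_{jk}-p_k)}{p_k(1-p_k)}}
#' with genotypes coded 0, 1/2, 1 (half the allele-1 count) and \eqn{p_k} the
#' frequency of the "+" (allele 1) allele. Under Hardy-Weinberg equilibrium
#' E[(x - p)^2] = pq/2, so unrelated individuals have diagonal entries near
#' 0.5 and off-diagonal entries near 0. Missing dosages are mean-imputed per
#' SNP before centring.
#'
#' @param g A [genotype_matrix()] with no monomorphic SNPs.
#' @return An object of class `grm`: list with `matrix` (n x n symmetric),
#'   `sample_ids` and `n_snps`.
#' @export
build_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  fr <- snp_freq(g)
  mono <- which(!(fr$allele1_freq > 0 & fr$allele1_freq < 1) | is.nan(fr$allele1_freq))
  if (length(mono) > 0) {
    abort(paste0(
      "Monomorphic SNP(s) in GRM input: ",
      paste(head(fr$snp[mono], 5), collapse = ", "),
      if (length(mono) > 5) sprintf(" (and %d more)", length(mono) - 5) else ""
    ))
  }
  p <- fr$allele1_freq
  x <- dosage_half(g)
  # mean imputation on the half-count scale
  if (anyNA(x)) {
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- p[na_idx[, 2]]
  }
  w <- sweep(x, 2, p, "-")
  w <- sweep(w, 2, sqrt(p * (1 - p)), "/")
  mat <- tcrossprod(w) / ncol(x)
  mat <- (mat + t(mat)) / 2
  dimnames(mat) <- list(g$sample_ids, g$sample_ids)
  structure(
    list(matrix = mat, sample_ids = g$sample_ids, n_snps = ncol(x)),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals from %d SNPs; mean diagonal %.3f\n",
              nrow(x$matrix), x$n_snps, mean(diag(x$matrix))))
  invisible(x)
}

#' Eigendecomposition of a GRM, with PSD floor and unit-diagonal scaling
#'
#' The identity-by-state coefficients of [build_grm()] are kinship-scale
#' (mean diagonal near 0.5 under Hardy-Weinberg). For the mixed model the
#' matrix is rescaled to unit mean diagonal so that `sigma_g2` is the
#' per-individual additive variance and `h2` the fraction of phenotypic
#' variance — the usual genomic-heritability scale. Eigenvalues below
#' `floor` are raised to `floor` (default 0), guaranteeing a positive
#' semi-definite covariance for the single-component REML rotation.
#'
#' @param grm A [build_grm()] result.
#' @param floor Minimum eigenvalue (applied before rescaling).
#' @return List with `values`, `vectors` (as [base::eigen()]) of the
#'   rescaled matrix, plus `scale` (the mean diagonal divided out).
#' @export
grm_eigen <- function(grm, floor = 0) {
  stopifnot(inherits(grm, "grm"))
  eg <- eigen(grm$matrix, symmetric = TRUE)
  sc <- mean(diag(grm$matrix))
  if (!is.finite(sc) || sc <= 0) abort("GRM has non-positive mean diagonal.")
  eg$values <- pmax(eg$values, floor) / sc
  eg$scale <- sc
  eg
}
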