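#' Genotype matrix container
#'
#' Bundles an individuals-by-markers dosage matrix with its marker map and
#' sample identifiers. Dosages count copies of allele 1 (the "+" allele) and
#' take values 0, 1, 2 or `NA` for a missing call. The identity-by-state
#' relationship matrix uses the half-count coding 0, 1/2, 1, which is exposed
#' as a view via [dosage_half()].
#'
#' @param dosage Integer or numeric matrix, individuals in rows, SNPs in
#'   columns, entries in `{0, 1, 2, NA}`.
#' @param snp_map Data frame with one row per SNP: columns `snp`, `chr`,
#'   `pos` (base pairs), `allele1`, `allele2`.
#' @param sample_ids Character vector of unique individual identifiers,
#'   one per row of `dosage`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snp_map, sample_ids) {
  dosage <- as.matrix(dosage)
  snp_map <- tibble::as_tibble(snp_map)
  sample_ids <- as.character(sample_ids)
  if (nrow(dosage) != length(sample_ids)) {
    abort("`dosage` rows must match `sample_ids` length.")
  }
  if (ncol(dosage) != nrow(snp_map)) {
    abort("`dosage` columns must match `snp_map` rows.")
  }
  needed <- c("snp", "chr", "pos", "allele1", "allele2")
  missing_cols <- setdiff(needed, names(snp_map))
  if (length(missing_cols) > 0) {
    abort(paste0("`snp_map` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(snp_map$snp)) abort("SNP ids must be unique.")
  if (anyDuplicated(sample_ids)) abort("Sample ids must be unique.")
  if (any(snp_map$pos < 0)) abort("Positions must be non-negative.")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) abort("Dosages must be 0, 1, 2 or NA.")
  dimnames(dosage) <- list(sample_ids, snp_map$snp)
  structure(
    list(dosage = dosage, snp_map = snp_map, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d SNPs on %d chromosome(s)\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$snp_map$chr))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Half-count genotype view
#'
#' Returns the dosage matrix recoded to 0, 1/2, 1 — the coding used by the
#' identity-by-state relationship matrix.
#'
#' @param g A [genotype_matrix()].
#' @return A numeric matrix.
#' @export
dosage_half <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  g$dosage / 2
}

#' Per-SNP allele frequency and minor allele frequency
#'
#' Frequencies are computed from non-missing calls only. `allele1_freq` is the
#' frequency of allele 1 (the allele whose copies the dosage counts); `maf` is
#' `pmin(p, 1 - p)`.
#'
#' @param g A [genotype_matrix()].
#' @return A tibble with columns `snp`, `allele1_freq`, `maf`, `call_rate`.
#' @export
snp_freq <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_called <- colSums(!is.na(g$dosage))
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  tibble::tibble(
    snp = g$snp_map$snp,
    allele1_freq = p,
    maf = pmin(p, 1 - p),
    call_rate = n_called / nrow(g$dosage)
  )
}

#' Subset a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @param snps Character vector of SNP ids, or logical/integer index over SNPs.
#' @param samples Character vector of sample ids, or logical/integer index.
#' @return A [genotype_matrix()] restricted to the requested markers/samples.
#' @export
subset_genotypes <- function(g, snps = NULL, samples = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  j <- seq_len(ncol(g$dosage))
  i <- seq_len(nrow(g$dosage))
  if (!is.null(snps)) {
    if (is.character(snps)) {
      j <- match(snps, g$snp_map$snp)
      if (anyNA(j)) {
        abort(paste0("Unknown SNP id(s): ", paste(snps[is.na(j)], collapse = ", ")))
      }
    } else {
      j <- seq_len(ncol(g$dosage))[snps]
    }
  }
  if (!is.null(samples)) {
    i <- if (is.character(samples)) match(samples, g$sample_ids) else seq_len(nrow(g$dosage))[samples]
    if (is.character(samples) && anyNA(i)) {
      abort("Unknown sample id(s) in `samples`.")
    }
  }
  genotype_matrix(
    g$dosage[i, j, drop = FALSE],
    g$snp_map[j, , drop = FALSE],
    g$sample_ids[i]
  )
}
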