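#' Build an association weight matrix (AWM) around a key phenotype
#'
#' Selects SNPs that are associated with the key trait (`p <= p_key`) or —
#' under the default OR rule — with at least `min_other_traits` other traits
#' (`p < p_other`), and that lie closer than `gene_dist_bp` (strict) to their
#' nearest annotated gene. Each retained gene contributes one row: among the
#' passing SNPs whose nearest gene it is, the SNP with the smallest key-trait
#' P is chosen (ties: larger absolute key-trait z, then lowest genomic
#' position). Cells hold the standardized, genomic-control-rescaled SNP
#' effect z for every trait; a missing trait fit yields 0 with the mask
#' recorded. The Ap statistic — the average number of non-key traits
#' associated (`p <= p_key`) with the key-associated SNPs — is computed over
#' the key-associated SNP set.
#'
#' @param assoc Multi-trait association tibble (see [gwas_scan()]) with
#'   columns `snp`, `chr`, `pos`, `trait`, `p_gc`, `z_gc`.
#' @param genes Gene annotation tibble (`gene`, `chr`, `start`, `end`,
#'   1-based inclusive).
#' @param key_trait Key phenotype label.
#' @param p_key Inclusion threshold on the key trait (inclusive `<=`).
#' @param p_other Threshold on other traits (strict `<`).
#' @param min_other_traits Minimum number of other associated traits.
#' @param gene_dist_bp Maximum distance to the nearest gene (strict `<`).
#' @param rule `"or"` (default) admits SNPs by either clause; `"and"`
#'   requires both.
#' @return Object of class `awm`: list with `matrix` (genes x traits of z),
#'   `info` (tibble `gene`, `snp`, `chr`, `pos`, `p_key`, `distance`),
#'   `key_trait`, `ap`, `mask` (logical matrix, TRUE where z was observed)
#'   and the selection parameters.
#' @export
build_awm <- function(assoc, genes, key_trait, p_key = 0.05, p_other = 0.05,
                      min_other_traits = 3, gene_dist_bp = 10000,
                      rule = c("or", "and")) {
  rule <- match.arg(rule)
  traits <- sort(unique(assoc$trait))
  if (!key_trait %in% traits) {
    abort(paste0("Unknown key trait: ", key_trait))
  }
  p_wide <- tidyr::pivot_wider(
    dplyr::select(assoc, "snp", "chr", "pos", "trait", "p_gc"),
    names_from = "trait", values_from = "p_gc"
  )
  z_wide <- tidyr::pivot_wider(
    dplyr::select(assoc, "snp", "trait", "z_gc"),
    names_from = "trait", values_from = "z_gc"
  )
  other <- setdiff(traits, key_trait)
  pk <- p_wide[[key_trait]]
  p_other_mat <- as.matrix(p_wide[, other, drop = FALSE])
  n_other <- rowSums(p_other_mat < p_other, na.rm = TRUE)

  key_assoc <- !is.na(pk) & pk <= p_key
  clause_other <- n_other >= min_other_traits
  pass <- if (rule == "or") key_assoc | clause_other else key_assoc & clause_other

  # Ap over the key-associated SNPs, counting other traits at p <= p_key
  ap <- if (any(key_assoc)) {
    mean(rowSums(p_other_mat[key_assoc, , drop = FALSE] <= p_key, na.rm = TRUE))
  } else NA_real_

  # nearest gene within gene_dist_bp (strict) of each passing SNP
  snp_tab <- dplyr::filter(
    dplyr::select(p_wide, "snp", "chr", "pos"), pass
  )
  if (nrow(snp_tab) == 0) abort("No SNP passes the AWM selection filters.")
  near <- map_snps_to_genes(snp_tab, genes, flank_bp = gene_dist_bp - 1)
  near <- dplyr::left_join(near, snp_tab, by = "snp")
  near <- dplyr::arrange(near, .data$distance, .data$gene)
  near <- dplyr::distinct(near, .data$snp, .keep_all = TRUE)  # nearest gene per SNP
  if (nrow(near) == 0) abort("No SNP passes the AWM selection filters.")

  sel <- dplyr::left_join(
    near,
    tibble::tibble(snp = p_wide$snp, p_key = pk,
                   z_key = z_wide[[key_trait]]),
    by = "snp"
  )
  # one SNP per gene: smallest key P, then larger |z_key|, then position
  sel <- dplyr::arrange(
    sel, .data$gene, .data$p_key, dplyr::desc(abs(.data$z_key)),
    .data$chr, .data$pos
  )
  sel <- dplyr::distinct(sel, .data$gene, .keep_all = TRUE)
  sel <- dplyr::arrange(sel, .data$chr, .data$pos, .data$gene)

  zi <- match(sel$snp, z_wide$snp)
  zmat <- as.matrix(z_wide[zi, traits, drop = FALSE])
  rownames(zmat) <- sel$gene
  mask <- !is.na(zmat)
  zmat[!mask] <- 0
  if (any(!is.finite(zmat))) abort("Non-finite standardized effect in AWM.")

  structure(
    list(
      matrix = zmat, mask = mask,
      info = dplyr::select(sel, "gene", "snp", "chr", "pos", "p_key", "distance"),
      key_trait = key_trait, ap = ap,
      params = list(p_key = p_key, p_other = p_other,
                    min_other_traits = min_other_traits,
                    gene_dist_bp = gene_dist_bp, rule = rule)
    ),
    class = "awm"
  )
}

#' @export
print.awm <- function(x, ...) {
  cat(sprintf(
    "<awm> %d genes x %d traits, key trait %s, Ap = %.2f\n",
    nrow(x$matrix), ncol(x$matrix), x$key_trait, x$ap
  ))
  invisible(x)
}

#' @rdname build_awm
#' @param x An `awm`.
#' @param ... Unused.
#' @export
tidy.awm <- function(x, ...) {
  out <- tibble::as_tibble(x$matrix)
  dplyr::bind_cols(tibble::tibble(gene = rownames(x$matrix)), out)
}

#' Hierarchical clustering of traits on AWM columns
#'
#' Distance between traits is 1 minus the Pearson correlation of their AWM
#' columns; agglomeration uses average linkage by default, as is customary
#' for correlation-screened trait panels.
#'
#' @param awm An [build_awm()] result (needs at least 2 traits).
#' @param k Number of clusters for the cut (default 3).
#' @param method Agglomeration method passed to [stats::hclust()].
#' @return Object of class `trait_clustering`: list with `hclust`,
#'   `clusters` (tibble `trait`, `cluster`) and the correlation matrix.
#' @export
cluster_traits <- function(awm, k = 3, method = "average") {
  stopifnot(inherits(awm, "awm"))
  z <- awm$matrix
  if (ncol(z) < 2) abort("Need at least 2 traits to cluster.")
  sds <- apply(z, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant AWM column for trait(s): ",
                 paste(colnames(z)[sds == 0], collapse = ", ")))
  }
  r <- cor(z)
  hc <- hclust(as.dist(1 - r), method = method)
  k <- min(k, ncol(z))
  cl <- cutree(hc, k = k)
  structure(
    list(
      hclust = hc,
      clusters = tibble::tibble(trait = names(cl), cluster = unname(cl)),
      correlation = r
    ),
    class = "trait_clustering"
  )
}

#' @export
print.trait_clustering <- function(x, ...) {
  cat(sprintf("<trait_clustering> %d traits in %d clusters\n",
              nrow(x$clusters), length(unique(x$clusters$cluster))))
  invisible(x)
}

#' Permutation test for the variance captured by the AWM SNPs
#'
#' The observed statistic is the fraction of (covariate-adjusted) phenotypic
#' variance of the key trait explained by a relationship matrix restricted to
#' the AWM SNPs, i.e. sigma_g2/(sigma_g2 + sigma_e2) from [fit_polygenic()].
#' The null distribution repeats the fit on `n_replicates` equally sized SNP
#' sets sampled without replacement from the panel (excluding the observed
#' set by default). The empirical P is `(1 + #{null >= observed}) / (R + 1)`,
#' reported as "< 1/(R+1)" when the observed value exceeds every replicate.
#'
#' @inheritParams fit_polygenic
#' @param genotypes The full [genotype_matrix()] panel.
#' @param awm_snps Character vector of the AWM-selected SNP ids.
#' @param n_replicates Number of random SNP sets (default 10000).
#' @param seed Integer seed for the replicate draws.
#' @param exclude_observed Exclude the AWM SNPs from the sampling pool.
#' @return Object of class `permutation_report`.
#' @export
variance_explained_permutation <- function(data, trait, genotypes, awm_snps,
                                           covariates = c("herd_date", "parity_class", "dim_class"),
                                           n_replicates = 10000, seed = 1L,
                                           exclude_observed = TRUE) {
  if (n_replicates < 1) abort("`n_replicates` must be at least 1.")
  all_snps <- genotypes$snp_map$snp
  if (!all(awm_snps %in% all_snps)) abort("`awm_snps` must be genotyped SNPs.")
  fr <- snp_freq(genotypes)
  poly <- fr$snp[fr$allele1_freq > 0 & fr$allele1_freq < 1]
  awm_snps <- intersect(awm_snps, poly)
  s <- length(awm_snps)
  pool <- if (exclude_observed) setdiff(poly, awm_snps) else poly
  if (s > length(pool)) abort("SNP pool smaller than the AWM set.")

  # standardized half-count genotypes once; per-set GRM is a cross-product
  covariates <- intersect(covariates, names(data))
  df <- data[, c("id", trait, covariates), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  gsx <- subset_genotypes(genotypes, samples = df$id)
  frs <- snp_freq(gsx)
  usable <- frs$allele1_freq > 0 & frs$allele1_freq < 1
  x <- dosage_half(gsx)
  if (anyNA(x)) {
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- frs$allele1_freq[na_idx[, 2]]
  }
  w <- sweep(x, 2, frs$allele1_freq, "-")
  w <- sweep(w, 2, sqrt(frs$allele1_freq * (1 - frs$allele1_freq)), "/")
  colnames(w) <- gsx$snp_map$snp
  y <- as.numeric(df[[trait]])
  X <- .design_matrix(df, covariates)

  h2_of <- function(snp_ids) {
    snp_ids <- snp_ids[snp_ids %in% colnames(w)[usable]]
    K <- tcrossprod(w[, snp_ids, drop = FALSE]) / length(snp_ids)
    .reml_h2(K, y, X)
  }
  observed <- h2_of(awm_snps)
  set.seed(seed)
  null <- vapply(seq_len(n_replicates), function(r) h2_of(sample(pool, s)),
                 numeric(1))
  n_ge <- sum(null >= observed)
  emp_p <- (1 + n_ge) / (n_replicates + 1)
  structure(
    list(
      observed_var_fraction = observed,
      null_mean = mean(null),
      null_distribution = null,
      empirical_p = emp_p,
      p_label = if (n_ge == 0) sprintf("< %.3g", 1 / (n_replicates + 1)) else
        sprintf("%.4g", emp_p),
      n_replicates = n_replicates,
      n_snps = s
    ),
    class = "permutation_report"
  )
}

# minimal REML h2 for a fixed kinship matrix (used by the permutation test)
.reml_h2 <- function(K, y, X) {
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0) / mean(diag(K))
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)
  n <- length(y)
  p <- ncol(X)
  opt <- optimize(function(h2) .reml_nll(h2, ys, Xs, d, n, p),
                  interval = c(0, 0.999), tol = 1e-8)
  cand <- c(opt$minimum, 0, 0.999)
  nll <- vapply(cand, function(h2) .reml_nll(h2, ys, Xs, d, n, p), numeric(1))
  cand[which.min(nll)]
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf(
    "<permutation_report> observed %.3f vs null mean %.3f over %d replicates (P %s)\n",
    x$observed_var_fraction, x$null_mean, x$n_replicates, x$p_label
  ))
  invisible(x)
}

#' @rdname variance_explained_permutation
#' @param x A `permutation_report`.
#' @param ... Unused.
#' @export
glance.permutation_report <- function(x, ...) {
  tibble::tibble(
    observed_var_fraction = x$observed_var_fraction,
    null_mean = x$null_mean,
    empirical_p = x$empirical_p,
    n_replicates = x$n_replicates,
    n_snps = x$n_snps
  )
}
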