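GC_MEDIAN_CHI2 <- 0.4549364  # median of a 1-df chi-square

#' GRAMMAR residual association scan with genomic control
#'
#' Regresses the GRAMMAR residuals from [fit_polygenic()] on each SNP dosage
#' (ordinary least squares), then applies two calibrations:
#'
#' * the GRAMMAR-gamma recalibration: scalar factors that undo the deflation
#'   caused by regressing on BLUP residuals. With
#'   \eqn{\Sigma = h^2 K + (1-h^2)I} the fitted correlation structure and
#'   \eqn{\rho = \frac{1}{M}\sum_k \frac{\tilde g_k' \Sigma^{-1} \tilde g_k}
#'   {\tilde g_k' \tilde g_k}}, effects are divided by
#'   \eqn{\gamma = (1-h^2)\rho} (restoring unbiasedness) and the naive
#'   \eqn{\chi^2} by \eqn{\gamma_{test} = n\rho / \mathrm{tr}(\Sigma^{-1})}
#'   (restoring the score-test scale); the SE is then derived as
#'   \eqn{|\beta|/\sqrt{\chi^2_{GC}}} so that \eqn{z = \beta/SE} matches the
#'   corrected statistic exactly;
#' * genomic control: \eqn{\lambda = \mathrm{median}(\chi^2)/0.4549}; the
#'   corrected P comes from \eqn{\chi^2/\lambda}. Because GRAMMAR is
#'   conservative, \eqn{\lambda} below 1 is used as estimated by default so
#'   that the correction can inflate as well as deflate;
#'   `gc_floor_lambda = TRUE` restricts the correction to deflation only.
#'
#' Zero-variance SNPs are reported with `NA` statistics, never dropped.
#' Missing dosages are excluded pairwise per SNP.
#'
#' @param fit A [fit_polygenic()] result.
#' @param genotypes A [genotype_matrix()] covering the fit's samples.
#' @param gamma_correct Apply the GRAMMAR-gamma recalibration (default TRUE).
#' @param gc_floor_lambda Floor lambda at 1 for the P-value correction.
#' @return A tibble of class `assoc_scan` with columns `snp`, `chr`, `pos`,
#'   `trait`, `beta`, `se`, `chi2`, `p_raw`, `p_gc`, `z_gc`, `maf`,
#'   `snp_var`, `pct_va`, and attributes `lambda` (unfloored), `lambda_used`,
#'   `gamma`, `sigma_g2`, `h2`, `n`.
#' @export
grammar_scan <- function(fit, genotypes, gamma_correct = TRUE,
                         gc_floor_lambda = FALSE) {
  stopifnot(inherits(fit, "polygenic_fit"), inherits(genotypes, "genotype_matrix"))
  g <- subset_genotypes(genotypes, samples = fit$sample_ids)
  e <- as.numeric(fit$residuals)
  n <- length(e)
  X <- g$dosage
  m <- ncol(X)

  has_na <- anyNA(X)
  xbar <- colMeans(X, na.rm = TRUE)
  if (!has_na) {
    Xc <- sweep(X, 2, xbar, "-")
    ec <- e - mean(e)
    sxx <- colSums(Xc^2)
    sxy <- as.numeric(crossprod(Xc, ec))
    see <- sum(ec^2)
    nn <- rep(n, m)
  } else {
    sxx <- sxy <- see_v <- numeric(m)
    nn <- integer(m)
    Xc <- sweep(X, 2, xbar, "-")
    Xc[is.na(Xc)] <- 0
    for (j in seq_len(m)) {
      ok <- !is.na(X[, j])
      xj <- X[ok, j]
      ej <- e[ok]
      xj <- xj - mean(xj)
      ej <- ej - mean(ej)
      sxx[j] <- sum(xj^2)
      sxy[j] <- sum(xj * ej)
      see_v[j] <- sum(ej^2)
      nn[j] <- sum(ok)
    }
  }

  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  if (!has_na) {
    rss <- see - beta * sxy
  } else {
    rss <- see_v - beta * sxy
  }
  s2 <- rss / pmax(nn - 2, 1)
  se <- ifelse(sxx > 0 & s2 > 0, sqrt(s2 / sxx), NA_real_)
  chi2 <- (beta / se)^2

  gamma <- 1
  gamma_test <- 1
  if (gamma_correct) {
    # effect-size deflation: E[beta_GRAMMAR] = gamma * beta with
    # gamma = (sigma_e2/sigma2) * mean_k (x_k' Sigma^-1 x_k)/(x_k' x_k);
    # test-statistic deflation: chi2_GRAMMAR ~ gamma_test * chi2_score with
    # gamma_test = mean_k n (x_k' Sigma^-1 x_k) / (x_k' x_k tr(Sigma^-1));
    # Sigma = h2 K + (1 - h2) I is the fitted correlation structure
    A <- crossprod(fit$eigenvectors, Xc)
    num <- colSums(A^2 / fit$weights)
    den <- colSums(Xc^2)
    ok <- den > 0 & is.finite(num)
    if (any(ok)) {
      ratio <- mean(num[ok] / den[ok])
      gamma <- (1 - fit$h2) * ratio
      gamma_test <- n * ratio / sum(1 / fit$weights)
    }
    beta <- beta / gamma
    chi2 <- chi2 / gamma_test
  }

  lambda <- median(chi2, na.rm = TRUE) / GC_MEDIAN_CHI2
  lambda_used <- if (gc_floor_lambda) max(1, lambda) else lambda
  p_raw <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p_gc <- pchisq(chi2 / lambda_used, df = 1, lower.tail = FALSE)
  z_gc <- sign(beta) * sqrt(chi2 / lambda_used)
  # SE kept consistent with the corrected effect and the GC statistic
  se <- ifelse(is.finite(chi2) & chi2 > 0, abs(beta) / sqrt(chi2 / lambda_used), se)

  fr <- snp_freq(g)
  snp_var <- snp_variance(fr$allele1_freq, beta)
  pct_va <- if (fit$sigma_g2 > 0) 100 * snp_var / fit$sigma_g2 else rep(NA_real_, m)

  out <- tibble::tibble(
    snp = g$snp_map$snp, chr = g$snp_map$chr, pos = g$snp_map$pos,
    trait = fit$trait,
    beta = beta, se = se, chi2 = chi2, p_raw = p_raw, p_gc = p_gc,
    z_gc = z_gc, maf = fr$maf, snp_var = snp_var, pct_va = pct_va
  )
  class(out) <- c("assoc_scan", class(out))
  attr(out, "lambda") <- lambda
  attr(out, "lambda_used") <- lambda_used
  attr(out, "gamma") <- gamma
  attr(out, "gamma_test") <- gamma_test
  attr(out, "sigma_g2") <- fit$sigma_g2
  attr(out, "h2") <- fit$h2
  attr(out, "n") <- n
  out
}

#' @rdname grammar_scan
#' @param x An `assoc_scan`.
#' @param ... Unused.
#' @export
glance.assoc_scan <- function(x, ...) {
  tibble::tibble(
    trait = x$trait[1], n_snps = nrow(x), lambda = attr(x, "lambda"),
    gamma = attr(x, "gamma"), sigma_g2 = attr(x, "sigma_g2"),
    h2 = attr(x, "h2"), n = attr(x, "n"),
    n_significant = sum(x$p_gc < 5e-5, na.rm = TRUE)
  )
}

#' SNP additive variance
#'
#' Variance contributed by a biallelic SNP with allele frequency `p` and
#' additive allele-substitution effect `a` (per dosage unit on the 0/1/2
#' scale): \eqn{2pqa^2}.
#'
#' @param p Allele frequency in `[0, 1]` (either allele; the formula is
#'   symmetric).
#' @param a Additive effect.
#' @return `2 * p * (1 - p) * a^2`, vectorised.
#' @export
snp_variance <- function(p, a) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1].")
  2 * p * (1 - p) * a^2
}

#' Per-trait GWAS over a set of traits
#'
#' Runs [fit_polygenic()] and [grammar_scan()] for each trait and binds the
#' scans. Traits are fitted independently; results do not depend on trait
#' order.
#'
#' @inheritParams fit_polygenic
#' @inheritParams grammar_scan
#' @param traits Character vector of trait columns; defaults to all columns
#'   named `trait_*`.
#' @return A tibble of class `assoc_scan` over all traits with a
#'   `variance_components` attribute (one [glance()] row per trait).
#' @export
gwas_scan <- function(data, genotypes, grm, traits = NULL,
                      covariates = c("herd_date", "parity_class", "dim_class"),
                      gamma_correct = TRUE, gc_floor_lambda = FALSE) {
  if (is.null(traits)) traits <- grep("^trait_", names(data), value = TRUE)
  if (length(traits) == 0) abort("No trait columns found.")
  eig <- NULL
  if (all(complete.cases(data[, c("id", traits, intersect(covariates, names(data)))])) &&
      identical(data$id, grm$sample_ids)) {
    eig <- grm_eigen(grm)
  }
  scans <- lapply(traits, function(tr) {
    fit <- fit_polygenic(data, tr, grm, covariates = covariates, eig = eig)
    sc <- grammar_scan(fit, genotypes, gamma_correct = gamma_correct,
                       gc_floor_lambda = gc_floor_lambda)
    list(scan = sc, vc = glance(sc))
  })
  out <- dplyr::bind_rows(lapply(scans, `[[`, "scan"))
  class(out) <- c("assoc_scan", class(tibble::tibble()))
  attr(out, "variance_components") <- dplyr::bind_rows(lapply(scans, `[[`, "vc"))
  out
}

#' Conditional association scan on fixed lead SNPs
#'
#' Adds the dosages of `fixed_snps` to the fixed effects, refits the
#' polygenic model and rescans, mirroring the strategy of conditioning on
#' the most significant variants of a region to expose secondary signals.
#' With `fixed_snps = character(0)` this reduces exactly to the base scan.
#'
#' @inheritParams fit_polygenic
#' @inheritParams grammar_scan
#' @param fixed_snps Character vector of SNP ids to condition on; collinear
#'   dosage columns are dropped with a warning. Missing dosages are
#'   mean-imputed for the design matrix.
#' @return List of class `conditional_scan`: `assoc` (conditional scan),
#'   `fit` (conditional fit), `base_fit`, and `delta`, a one-row tibble with
#'   the relative change of `sigma_g2` and `h2` versus the unconditional
#'   model.
#' @export
conditional_scan <- function(data, trait, genotypes, grm, fixed_snps,
                             covariates = c("herd_date", "parity_class", "dim_class"),
                             gamma_correct = TRUE, gc_floor_lambda = FALSE) {
  base_fit <- fit_polygenic(data, trait, grm, covariates = covariates)
  if (length(fixed_snps) > 0) {
    j <- match(fixed_snps, genotypes$snp_map$snp)
    if (anyNA(j)) {
      abort(paste0("Fixed SNP(s) absent from map: ",
                   paste(fixed_snps[is.na(j)], collapse = ", ")))
    }
    idx <- match(data$id, genotypes$sample_ids)
    snp_cols <- genotypes$dosage[idx, j, drop = FALSE]
    for (cc in seq_len(ncol(snp_cols))) {
      col <- snp_cols[, cc]
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      data[[paste0(".cond_", fixed_snps[cc])]] <- col
    }
    covariates <- c(covariates, paste0(".cond_", fixed_snps))
  }
  fit <- fit_polygenic(data, trait, grm, covariates = covariates)
  assoc <- grammar_scan(fit, genotypes, gamma_correct = gamma_correct,
                        gc_floor_lambda = gc_floor_lambda)
  delta <- tibble::tibble(
    trait = trait,
    sigma_g2_base = base_fit$sigma_g2, sigma_g2_cond = fit$sigma_g2,
    sigma_g2_change_pct = 100 * (fit$sigma_g2 - base_fit$sigma_g2) /
      base_fit$sigma_g2,
    h2_base = base_fit$h2, h2_cond = fit$h2,
    h2_change = fit$h2 - base_fit$h2
  )
  structure(
    list(assoc = assoc, fit = fit, base_fit = base_fit, delta = delta),
    class = "conditional_scan"
  )
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage columns (composite,
#' genotype-based LD), computed on individuals with both calls present.
#'
#' @param g A [genotype_matrix()].
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g, snp_a, snp_b) {
  stopifnot(inherits(g, "genotype_matrix"))
  j <- match(c(snp_a, snp_b), g$snp_map$snp)
  if (anyNA(j)) abort("Unknown SNP id in `ld_r2()`.")
  x <- g$dosage[, j[1]]
  y <- g$dosage[, j[2]]
  ok <- !is.na(x) & !is.na(y)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("Monomorphic SNP passed to `ld_r2()`.")
  }
  cor(x[ok], y[ok])^2
}
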