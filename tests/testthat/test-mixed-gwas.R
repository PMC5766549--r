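test_that("GRM entries match the IBS formula on forced cases", {
  # one SNP, p = 0.5: x_i = x_j = 1 (half-coded) gives f = (0.5*0.5)/0.25 = 1
  g <- genotype_matrix(
    matrix(c(2L, 2L, 0L, 0L), ncol = 1),
    tibble::tibble(snp = "s1", chr = 1, pos = 10, allele1 = "A", allele2 = "B"),
    c("a", "b", "c", "d")
  )
  grm <- build_grm(g)
  expect_equal(grm$matrix["a", "b"], 1)
  expect_equal(grm$matrix["a", "c"], -1)
  expect_equal(grm$matrix["a", "a"], 1)
})

test_that("GRM moments match HWE expectation and coding is invariant", {
  cfg <- sim_config(n_individuals = 150, n_snps = 2000, n_chromosomes = 2,
                    maf_range = c(0.1, 0.5), n_traits = 2,
                    trait_clusters = c(1, 2), h2 = c(0.2, 0.2),
                    n_herds = 4, seed = 17)
  g <- simulate_genotypes(cfg)
  grm <- build_grm(g)
  expect_equal(mean(diag(grm$matrix)), 0.5, tolerance = 0.02)
  expect_equal(mean(grm$matrix[upper.tri(grm$matrix)]), 0, tolerance = 0.01)
  expect_lt(max(abs(grm$matrix - t(grm$matrix))), 1e-10)

  # full {0,1,2} coding with its own standardisation differs by a constant
  # factor of 2 which the unit-diagonal normalisation removes
  p <- colMeans(g$dosage) / 2
  w_full <- sweep(sweep(g$dosage, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  grm_full <- tcrossprod(w_full) / ncol(g$dosage)
  norm_half <- grm$matrix / mean(diag(grm$matrix))
  norm_full <- grm_full / mean(diag(grm_full))
  expect_equal(norm_half, unname(norm_full), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("monomorphic SNPs are rejected by name", {
  g <- genotype_matrix(
    cbind(c(0L, 1L, 2L), c(2L, 2L, 2L)),
    tibble::tibble(snp = c("poly", "mono"), chr = 1, pos = c(1, 2),
                   allele1 = "A", allele2 = "B"),
    c("a", "b", "c")
  )
  expect_error(build_grm(g), "mono")
})

test_that("REML with an identity GRM reduces to OLS", {
  set.seed(4)
  n <- 120
  df <- tibble::tibble(
    id = sprintf("s%03d", 1:n),
    herd_date = sample(c("h1", "h2", "h3"), n, TRUE),
    trait_1 = rnorm(n)
  )
  df$trait_1 <- df$trait_1 + c(h1 = 0, h2 = 1, h3 = -1)[df$herd_date]
  grm <- structure(
    list(matrix = diag(n), sample_ids = df$id, n_snps = 0L), class = "grm"
  )
  fit <- fit_polygenic(df, "trait_1", grm, covariates = "herd_date")
  ols <- lm(trait_1 ~ herd_date, data = df)
  s2_ols <- sum(residuals(ols)^2) / ols$df.residual
  # sigma_g2 and sigma_e2 are not separately identifiable but their sum is
  expect_equal(fit$sigma_g2 + fit$sigma_e2, s2_ols, tolerance = 1e-6)
})

test_that("REML returns a null heritability for pure noise", {
  # small fixture (200 cows): average over noise draws to tame the
  # boundary-truncated sampling distribution
  co <- small_cohort()
  set.seed(8)
  h2_hat <- vapply(1:3, function(i) {
    df <- co$phenotypes
    df$noise <- rnorm(nrow(df))
    fit_polygenic(df, "noise", small_grm())$h2
  }, numeric(1))
  expect_lte(mean(h2_hat), 0.1)
})

test_that("REML recovers a moderate heritability on simulation", {
  h2_hat <- vapply(1:6, function(s) {
    cfg <- sim_config(n_individuals = 500, n_snps = 2000, n_chromosomes = 3,
                      n_traits = 2, trait_clusters = c(1, 2), h2 = c(0.5, 0.3),
                      n_herds = 6, seed = 500 + s)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(g, cfg)
    fit_polygenic(ph$phenotypes, "trait_1", build_grm(g))$h2
  }, numeric(1))
  expect_equal(mean(h2_hat), 0.5, tolerance = 0.1)
})

test_that("variance components expose tidy and glance views", {
  co <- small_cohort()
  fit <- fit_polygenic(co$phenotypes, "trait_2", small_grm())
  td <- tidy(fit)
  expect_identical(td$term, c("sigma_g2", "sigma_e2", "h2"))
  gl <- glance(fit)
  expect_equal(gl$h2, fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2))
  expect_identical(gl$n, nrow(co$phenotypes))
})

test_that("grammar scan flags zero-variance SNPs and keeps p in range", {
  co <- small_cohort()
  g <- co$genotypes
  dos <- g$dosage
  dos[, 5] <- 1L  # constant column
  g2 <- genotype_matrix(dos, g$snp_map, g$sample_ids)
  fit <- fit_polygenic(co$phenotypes, "trait_3", small_grm())
  sc <- grammar_scan(fit, g2)
  expect_identical(nrow(sc), ncol(dos))
  expect_true(is.na(sc$beta[5]))
  ok <- !is.na(sc$p_gc)
  expect_true(all(sc$p_gc[ok] > 0 & sc$p_gc[ok] <= 1))
  expect_true(all(sc$chi2[ok] >= 0))
  expect_true(all(sc$snp_var[ok] >= 0))
})

test_that("raw p-values are uniform under permuted residuals", {
  co <- small_cohort()
  fit <- fit_polygenic(co$phenotypes, "trait_4", small_grm())
  set.seed(14)
  fit$residuals <- sample(fit$residuals)
  sc <- grammar_scan(fit, co$genotypes, gamma_correct = FALSE)
  expect_gt(ks.test(sc$p_raw, "punif")$p.value, 0.01)
})

test_that("snp_variance evaluates 2pq a^2", {
  expect_equal(snp_variance(0.5, 1), 0.5)
  expect_equal(snp_variance(0, 3), 0)
  expect_equal(snp_variance(1, 3), 0)
  expect_equal(snp_variance(0.24, 2), 2 * 0.24 * 0.76 * 4)
  expect_error(snp_variance(1.2, 1), "0, 1")
})

test_that("ld_r2 matches a hand Pearson computation", {
  g <- genotype_matrix(
    cbind(c(0L, 1L, 2L, 2L), c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 2L),
          c(1L, 1L, 1L, 1L)),
    tibble::tibble(snp = c("a", "b", "a2", "const"), chr = 1, pos = 1:4,
                   allele1 = "A", allele2 = "B"),
    c("s1", "s2", "s3", "s4")
  )
  expect_equal(ld_r2(g, "a", "a2"), 1)
  expect_equal(ld_r2(g, "a", "b"), cor(c(0, 1, 2, 2), c(0, 1, 2, 0))^2)
  expect_error(ld_r2(g, "a", "const"), "Monomorphic")

  set.seed(3)
  r2 <- vapply(1:100, function(i) {
    cor(rbinom(1000, 2, 0.3), rbinom(1000, 2, 0.3))^2
  }, numeric(1))
  expect_lt(mean(r2), 0.01)
})

test_that("empty conditioning set reproduces the base scan", {
  co <- small_cohort()
  cs <- conditional_scan(co$phenotypes, "trait_2", co$genotypes, small_grm(),
                         fixed_snps = character(0))
  base <- grammar_scan(fit_polygenic(co$phenotypes, "trait_2", small_grm()),
                       co$genotypes)
  expect_equal(cs$assoc$p_gc, base$p_gc, tolerance = 1e-10)
  expect_equal(cs$delta$sigma_g2_change_pct, 0, tolerance = 1e-6)
})

test_that("conditioning on a null SNP leaves heritability unchanged", {
  drops <- vapply(1:3, function(s) {
    cfg <- sim_config(n_individuals = 250, n_snps = 600, n_chromosomes = 3,
                      n_traits = 2, trait_clusters = c(1, 2), h2 = c(0.4, 0.3),
                      n_herds = 6, seed = 300 + s)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(g, cfg)
    cs <- conditional_scan(ph$phenotypes, "trait_1", g, build_grm(g),
                           fixed_snps = "chr2_snp7")
    cs$delta$h2_change
  }, numeric(1))
  expect_lt(max(abs(drops)), 0.05)
})

test_that("scan results are independent of trait order", {
  co <- small_cohort()
  fwd <- gwas_scan(co$phenotypes, co$genotypes, small_grm(),
                   traits = c("trait_1", "trait_3"))
  rev <- gwas_scan(co$phenotypes, co$genotypes, small_grm(),
                   traits = c("trait_3", "trait_1"))
  f1 <- dplyr::filter(fwd, trait == "trait_1")
  r1 <- dplyr::filter(rev, trait == "trait_1")
  expect_equal(f1$p_gc, r1$p_gc)
})

test_that("autoplot produces ggplot objects", {
  sc <- small_assoc()
  expect_s3_class(autoplot(sc), "ggplot")
})
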