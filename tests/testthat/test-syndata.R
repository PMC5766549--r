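test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_individuals = 40, n_snps = 60, n_chromosomes = 3,
                    n_traits = 3, trait_clusters = c(1, 1, 2),
                    h2 = c(0.4, 0.3, 0.2), n_herds = 5, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$annotation, b$annotation)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
})

test_that("genotype draws respect allele-frequency and HWE structure", {
  cfg <- sim_config(n_individuals = 800, n_snps = 200, n_chromosomes = 2,
                    maf_range = c(0.5, 0.5), n_traits = 2,
                    trait_clusters = c(1, 2), h2 = c(0.2, 0.2),
                    n_herds = 4, seed = 5)
  g <- simulate_genotypes(cfg)
  # binomial(2, 0.5) has mean dosage 1
  expect_equal(mean(colMeans(g$dosage)), 1, tolerance = 0.02)
  # positions strictly increasing within chromosome
  for (cc in unique(g$snp_map$chr)) {
    expect_true(all(diff(g$snp_map$pos[g$snp_map$chr == cc]) > 0))
  }
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
})

test_that("zero LD decay gives independent adjacent SNPs", {
  cfg <- sim_config(n_individuals = 500, n_snps = 1001, n_chromosomes = 1,
                    maf_range = c(0.1, 0.5), n_traits = 2,
                    trait_clusters = c(1, 2), h2 = c(0.2, 0.2),
                    ld_decay = 0, n_herds = 4, seed = 9)
  g <- simulate_genotypes(cfg)
  r2 <- vapply(seq_len(1000), function(j) {
    suppressWarnings(cor(g$dosage[, j], g$dosage[, j + 1])^2)
  }, numeric(1))
  # independent pairs: E[r2] = 1/(n-1) ~ 0.002
  expect_lt(mean(r2, na.rm = TRUE), 0.01)

  cfg_ld <- sim_config(n_individuals = 500, n_snps = 301, n_chromosomes = 1,
                       maf_range = c(0.1, 0.5), n_traits = 2,
                       trait_clusters = c(1, 2), h2 = c(0.2, 0.2),
                       ld_decay = 0.8, n_herds = 4, seed = 9)
  gl <- simulate_genotypes(cfg_ld)
  r2l <- vapply(seq_len(300), function(j) {
    suppressWarnings(cor(gl$dosage[, j], gl$dosage[, j + 1])^2)
  }, numeric(1))
  expect_gt(mean(r2l, na.rm = TRUE), 0.2)
})

test_that("phenotype generator hits configured heritability and QTL share", {
  reps <- lapply(1:5, function(s) {
    cfg <- sim_config(n_individuals = 500, n_snps = 800, n_chromosomes = 4,
                      n_traits = 3, trait_clusters = c(1, 2, 3),
                      h2 = c(0.2, 0.5, 0.8),
                      qtl = list(list(chr = 1, snp_index = 10, traits = 2,
                                      var_frac = 0.4)),
                      n_herds = 8, seed = 100 + s)
    g <- simulate_genotypes(cfg)
    simulate_phenotypes(g, cfg)$truth
  })
  realized <- t(vapply(reps, function(tr) tr$traits$realized_h2, numeric(3)))
  expect_true(all(abs(colMeans(realized) - c(0.2, 0.5, 0.8)) < 0.05))

  # realized QTL share of the additive variance for trait_2
  shares <- vapply(seq_along(reps), function(i) {
    tr <- reps[[i]]
    cfg <- sim_config(n_individuals = 500, n_snps = 800, n_chromosomes = 4,
                      n_traits = 3, trait_clusters = c(1, 2, 3),
                      h2 = c(0.2, 0.5, 0.8),
                      qtl = list(list(chr = 1, snp_index = 10, traits = 2,
                                      var_frac = 0.4)),
                      n_herds = 8, seed = 100 + i)
    g <- simulate_genotypes(cfg)
    x <- g$dosage[, match(tr$qtl$snp, g$snp_map$snp)]
    var(x * tr$qtl$effect) / var(tr$genetic_values[, 2])
  }, numeric(1))
  expect_true(all(abs(shares - 0.4) < 0.10))
})

test_that("null heritability gives no genetic signal downstream", {
  h2_hat <- vapply(1:3, function(s) {
    cfg <- sim_config(n_individuals = 500, n_snps = 2000, n_chromosomes = 3,
                      n_traits = 2, trait_clusters = c(1, 2), h2 = c(0, 0),
                      n_herds = 6, seed = 20 + s)
    co <- simulate_cohort(cfg)
    stopifnot(all(co$truth$traits$realized_h2 == 0))
    fit_polygenic(co$phenotypes, "trait_1", build_grm(co$genotypes))$h2
  }, numeric(1))
  expect_lte(mean(h2_hat), 0.05)
})

test_that("a major QTL leaves a recoverable marginal effect", {
  co <- small_cohort()
  qtl <- co$truth$qtl
  j <- match(qtl$snp[1], co$genotypes$snp_map$snp)
  ols <- unname(coef(lm(co$phenotypes$trait_1 ~ co$genotypes$dosage[, j]))[2])
  expect_identical(sign(ols), unname(sign(qtl$effect[1])))
  expect_equal(ols, unname(qtl$effect[1]), tolerance = 0.5)
})

test_that("within-cluster residual correlation propagates to phenotypes", {
  cfg <- sim_config(n_individuals = 1000, n_snps = 300, n_chromosomes = 2,
                    n_traits = 3, trait_clusters = c(1, 1, 2),
                    within_cluster_corr = 0.9, h2 = c(0.1, 0.1, 0.1),
                    n_herds = 5, herd_sd = 0, parity_sd = 0, dim_sd = 0,
                    seed = 33)
  co <- simulate_cohort(cfg)
  r12 <- cor(co$phenotypes$trait_1, co$phenotypes$trait_2)
  r13 <- cor(co$phenotypes$trait_1, co$phenotypes$trait_3)
  expect_gt(r12, 0.6)
  expect_lt(abs(r13), 0.25)
})

test_that("toy annotation straddles the enrichment size filter", {
  cfg <- small_cohort()$config
  ann <- make_toy_annotation(cfg, snp_map = small_cohort()$genotypes$snp_map)
  sizes <- lengths(ann$gene_sets)
  expect_true(any(sizes == 10))  # boundary category, later excluded
  expect_true(any(sizes == 11))  # smallest retained size
  expect_true(all(ann$genes$start <= ann$genes$end))
  expect_true(all(unlist(ann$gene_sets) %in% ann$genes$gene))
  expect_true(all(ann$tf_catalog %in% ann$genes$gene))
  expect_gte(length(ann$tf_catalog), 3)
  ann2 <- make_toy_annotation(cfg, snp_map = small_cohort()$genotypes$snp_map)
  expect_identical(ann, ann2)
})

test_that("invalid QTL placement errors out", {
  cfg <- sim_config(n_individuals = 50, n_snps = 30, n_chromosomes = 3,
                    n_traits = 2, trait_clusters = c(1, 2), h2 = c(0.3, 0.3),
                    qtl = list(list(chr = 2, snp_index = 500, traits = 1,
                                    var_frac = 0.5)),
                    n_herds = 4, seed = 2)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_phenotypes(g, cfg), "absent")
})
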