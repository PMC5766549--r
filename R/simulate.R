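#' Simulate SNP genotypes for a synthetic cohort
#'
#' Draws per-SNP "+"-allele frequencies uniformly from `config$maf_range` and
#' builds haplotypes along each chromosome as a Markov chain: the allele at
#' marker k copies the allele at marker k-1 with probability `ld_decay`,
#' otherwise it is a fresh Bernoulli(p_k) draw (`ld_decay = 0` gives linkage
#' equilibrium). Cohort relatedness mimics an artificial-insemination dairy
#' population: each cow is assigned to one of `n_sires` paternal half-sib
#' families and receives a recombined gamete from her sire's two haplotypes
#' (switch probability `recomb_rate` per marker interval) plus an unrelated
#' dam haplotype drawn from the population process. This preserves per-site
#' Hardy-Weinberg proportions while creating the kinship signal a GRM-based
#' mixed model relies on. Map positions are strictly increasing within each
#' chromosome, with random inter-marker gaps on the scale of a medium-density
#' bovine chip.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps
  n_chr <- min(config$n_chromosomes, m)
  chr_sizes <- diff(floor(seq(0, m, length.out = n_chr + 1)))
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  n_sires <- min(config$n_sires, n)
  sire_of <- if (n_sires > 0) sample.int(n_sires, n, replace = TRUE) else integer(0)

  # Markov haplotype pool: rows are haplotypes, columns markers of one chr
  fresh_haps <- function(k, pc) {
    mc <- length(pc)
    h <- matrix(0L, k, mc)
    h[, 1] <- rbinom(k, 1L, pc[1])
    if (mc > 1) {
      for (j in 2:mc) {
        fresh <- rbinom(k, 1L, pc[j])
        if (config$ld_decay > 0) {
          copy <- rbinom(k, 1L, config$ld_decay) == 1L
          h[, j] <- ifelse(copy, h[, j - 1], fresh)
        } else {
          h[, j] <- fresh
        }
      }
    }
    h
  }

  dosage <- matrix(0L, n, m)
  map <- vector("list", n_chr)
  offset <- 0L
  for (cc in seq_len(n_chr)) {
    mc <- chr_sizes[cc]
    if (mc == 0) next
    idx <- offset + seq_len(mc)
    pc <- p[idx]
    mat <- fresh_haps(n, pc)
    if (n_sires > 0) {
      sire_haps <- fresh_haps(2L * n_sires, pc)
      # recombined paternal gamete: switch between the sire's haplotypes
      state <- cbind(rbinom(n, 1L, 0.5),
                     matrix(rbinom(n * (mc - 1L), 1L, config$recomb_rate),
                            n, mc - 1L))
      state <- t(apply(state, 1L, cumsum)) %% 2L
      if (mc == 1L) state <- matrix(state, n, 1L)
      row_idx <- 2L * (sire_of - 1L) + 1L + state  # n x mc haplotype rows
      pat <- matrix(sire_haps[cbind(as.vector(row_idx),
                                    rep(seq_len(mc), each = n))], n, mc)
    } else {
      pat <- fresh_haps(n, pc)
    }
    dosage[, idx] <- mat + pat
    gaps <- as.integer(round(runif(mc, 2e4, 8e4)))
    map[[cc]] <- tibble::tibble(
      snp = sprintf("chr%d_snp%d", cc, seq_len(mc)),
      chr = cc,
      pos = cumsum(gaps),
      allele1 = "A",
      allele2 = "B"
    )
    offset <- offset + mc
  }
  snp_map <- dplyr::bind_rows(map)
  g <- genotype_matrix(dosage, snp_map, sprintf("cow%04d", seq_len(n)))
  attr(g, "sire_of") <- sire_of
  g
}

#' Simulate phenotypes over a genotype matrix
#'
#' Builds each trait as the sum of herd-date, parity and days-in-milk class
#' effects, optional major-QTL effects, a polygenic value drawn from
#' N(0, K * sigma_g2) with K the unit-mean-diagonal rescaling (see
#' [grm_eigen()]) of the same identity-by-state relationship matrix the
#' analysis uses, and a residual. Per-trait variance (fixed effects
#' aside) is normalised to 1, so sigma_g2 = h2 and sigma_e2 = 1 - h2.
#' Residuals of traits sharing a cluster are correlated at
#' `within_cluster_corr`. Each QTL absorbs `var_frac` of the trait's additive
#' variance via an effect b = sqrt(var_frac * h2 / (2pq)) on the tagging SNP;
#' the polygenic term is scaled down to (1 - var_frac) * h2 so total additive
#' variance stays at h2.
#'
#' @param genotypes A [genotype_matrix()], typically from
#'   [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return A list with `phenotypes` (tibble: `id`, `herd_date`,
#'   `parity_class`, `dim_class`, `trait_1` ... `trait_k`) and `truth`
#'   (list: per-trait tibble `traits`, per-QTL tibble `qtl`, and the n x k
#'   matrix `genetic_values` of simulated total additive values).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  n <- nrow(genotypes$dosage)
  k <- config$n_traits
  trait_names <- sprintf("trait_%d", seq_len(k))

  herd <- sample.int(config$n_herds, n, replace = TRUE)
  parity <- sample.int(config$parity_classes, n, replace = TRUE)
  dimc <- sample.int(config$dim_classes, n, replace = TRUE)
  herd_eff <- rnorm(config$n_herds, 0, config$herd_sd)
  parity_eff <- rnorm(config$parity_classes, 0, config$parity_sd)
  dim_eff <- rnorm(config$dim_classes, 0, config$dim_sd)
  fixed <- herd_eff[herd] + parity_eff[parity] + dim_eff[dimc]

  # QTL bookkeeping: per trait, total additive fraction assigned to QTL
  qtl_rows <- list()
  qtl_contrib <- matrix(0, n, k)
  qtl_frac <- numeric(k)
  freq <- snp_freq(genotypes)
  for (q in config$qtl) {
    on_chr <- which(genotypes$snp_map$chr == q$chr)
    if (length(on_chr) < q$snp_index) {
      abort(sprintf("QTL position %d absent from chromosome %d map.", q$snp_index, q$chr))
    }
    j <- on_chr[q$snp_index]
    p <- freq$allele1_freq[j]
    x <- genotypes$dosage[, j]
    x[is.na(x)] <- 2 * p
    for (t in q$traits) {
      b <- sqrt(q$var_frac * config$h2[t] / (2 * p * (1 - p)))
      qtl_contrib[, t] <- qtl_contrib[, t] + b * (x - 2 * p)
      qtl_frac[t] <- qtl_frac[t] + q$var_frac
      qtl_rows[[length(qtl_rows) + 1]] <- tibble::tibble(
        snp = genotypes$snp_map$snp[j], chr = q$chr,
        pos = genotypes$snp_map$pos[j], trait = trait_names[t],
        effect = b, var_frac = q$var_frac
      )
    }
  }
  if (any(qtl_frac >= 1)) abort("QTL variance fractions for a trait must sum below 1.")

  # polygenic values share the analysis GRM; monomorphic sites are skipped
  poly <- matrix(0, n, k)
  poly_var <- config$h2 * (1 - qtl_frac)
  if (any(poly_var > 0)) {
    keep <- freq$allele1_freq > 0 & freq$allele1_freq < 1
    grm <- build_grm(subset_genotypes(genotypes, snps = which(keep)))
    eg <- grm_eigen(grm)  # unit-mean-diagonal scale, as used by the REML fit
    L <- eg$vectors %*% diag(sqrt(eg$values), n)
    for (t in seq_len(k)) {
      if (poly_var[t] > 0) poly[, t] <- sqrt(poly_var[t]) * (L %*% rnorm(n))
    }
  }

  # residuals: block-correlated across traits within clusters
  R <- diag(k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a != b && config$trait_clusters[a] == config$trait_clusters[b]) {
      R[a, b] <- config$within_cluster_corr
    }
  }
  sd_e <- sqrt(1 - config$h2)
  sigma_e <- diag(sd_e, k) %*% R %*% diag(sd_e, k)
  ce <- chol(sigma_e)
  resid <- matrix(rnorm(n * k), n, k) %*% ce

  genetic <- qtl_contrib + poly
  y <- fixed + genetic + resid
  colnames(genetic) <- trait_names

  phen <- tibble::tibble(
    id = genotypes$sample_ids,
    herd_date = sprintf("H%03d", herd),
    parity_class = sprintf("P%d", parity),
    dim_class = sprintf("D%02d", dimc)
  )
  for (t in seq_len(k)) phen[[trait_names[t]]] <- y[, t]

  truth <- list(
    traits = tibble::tibble(
      trait = trait_names,
      h2 = config$h2,
      cluster = config$trait_clusters,
      qtl_var_frac = qtl_frac,
      realized_h2 = apply(genetic, 2, var) /
        (apply(genetic, 2, var) + apply(resid, 2, var))
    ),
    qtl = if (length(qtl_rows)) dplyr::bind_rows(qtl_rows) else
      tibble::tibble(snp = character(), chr = integer(), pos = integer(),
                     trait = character(), effect = numeric(), var_frac = numeric()),
    genetic_values = genetic
  )
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_phenotypes()]
#' and [make_toy_annotation()] under one seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_cohort`: list with `genotypes`,
#'   `phenotypes`, `truth`, `annotation` (list: `genes`, `gene_sets`,
#'   `tf_catalog`) and the `config`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  ph <- simulate_phenotypes(g, config)
  ann <- make_toy_annotation(config, snp_map = g$snp_map)
  structure(
    list(genotypes = g, phenotypes = ph$phenotypes, truth = ph$truth,
         annotation = ann, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d cows, %d SNPs, %d traits, %d genes, seed %d\n",
    nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
    x$config$n_traits, nrow(x$annotation$genes), x$config$seed
  ))
  invisible(x)
}

#' Generate toy gene annotation, gene sets and a TF catalog
#'
#' Tiles gene intervals over the simulated marker map (including occasional
#' deliberately overlapping pairs), builds gene-set categories whose sizes
#' straddle the enrichment size filter, and flags a subset of genes as
#' transcription factors. Purely synthetic stand-ins for a genome annotation,
#' GO/KEGG-style category definitions and a TF compendium.
#'
#' @param config A [sim_config()].
#' @param snp_map Marker map tibble (`snp`, `chr`, `pos`); defaults to the map
#'   [simulate_genotypes()] would produce for `config`.
#' @param gene_length,gene_gap Mean gene length and inter-gene gap in bp.
#' @param set_sizes Integer vector of requested gene-set sizes (capped at the
#'   number of genes).
#' @param tf_fraction Fraction of genes flagged as transcription factors.
#' @return List with `genes` (tibble `gene`, `chr`, `start`, `end`; 1-based
#'   inclusive), `gene_sets` (named list of gene-id vectors) and `tf_catalog`
#'   (character vector).
#' @export
make_toy_annotation <- function(config, snp_map = NULL,
                                gene_length = 20000, gene_gap = 30000,
                                set_sizes = c(5L, 10L, 11L, 20L, 30L, 50L),
                                tf_fraction = 0.08) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(snp_map)) snp_map <- simulate_genotypes(config)$snp_map
  set.seed(config$seed + 2000L)
  genes <- list()
  for (cc in sort(unique(snp_map$chr))) {
    lo <- min(snp_map$pos[snp_map$chr == cc])
    hi <- max(snp_map$pos[snp_map$chr == cc])
    start <- max(1, lo - gene_length)
    i <- 0L
    rows <- list()
    while (start < hi + gene_length) {
      i <- i + 1L
      len <- max(1000, round(rnorm(1, gene_length, gene_length / 4)))
      rows[[i]] <- tibble::tibble(
        gene = sprintf("g%02d_%04d", cc, i),
        chr = cc, start = as.integer(start), end = as.integer(start + len - 1)
      )
      # every 7th gene overlaps its predecessor to exercise multi-assignment
      shift <- if (i %% 7L == 6L) -round(len / 4) else
        round(runif(1, gene_gap / 2, gene_gap * 1.5))
      start <- start + len + shift
    }
    genes[[length(genes) + 1]] <- dplyr::bind_rows(rows)
  }
  genes <- dplyr::bind_rows(genes)
  ids <- genes$gene
  set_sizes <- pmin(as.integer(set_sizes), length(ids))
  gene_sets <- lapply(seq_along(set_sizes), function(i) {
    sort(sample(ids, set_sizes[i]))
  })
  names(gene_sets) <- sprintf("SET_%02d", seq_along(gene_sets))
  n_tf <- max(3L, round(tf_fraction * length(ids)))
  tf_catalog <- sort(sample(ids, min(n_tf, length(ids))))
  list(genes = genes, gene_sets = gene_sets, tf_catalog = tf_catalog)
}
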