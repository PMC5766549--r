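# Shared fixtures and independent oracles, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small cohort with a 50%-Va QTL on trait_1, reused across files
small_cohort <- function() {
  cached("small_cohort", {
    cfg <- sim_config(
      n_individuals = 200, n_snps = 600, n_chromosomes = 4,
      maf_range = c(0.1, 0.5), n_traits = 4, trait_clusters = c(1, 1, 2, 2),
      within_cluster_corr = 0.6, h2 = c(0.5, 0.4, 0.3, 0.2),
      qtl = list(list(chr = 2, snp_index = 20, traits = 1, var_frac = 0.5)),
      n_herds = 8, parity_classes = 3, dim_classes = 4, seed = 42
    )
    simulate_cohort(cfg)
  })
}

small_grm <- function() cached("small_grm", build_grm(small_cohort()$genotypes))

small_assoc <- function() {
  cached("small_assoc", {
    co <- small_cohort()
    gwas_scan(co$phenotypes, co$genotypes, small_grm())
  })
}

# random valid correlation matrix (from a random data matrix, so PSD)
random_corr <- function(n_nodes, n_obs = n_nodes + 5) {
  x <- matrix(rnorm(n_obs * n_nodes), n_obs, n_nodes)
  r <- cor(x)
  dimnames(r) <- list(sprintf("n%02d", seq_len(n_nodes)),
                      sprintf("n%02d", seq_len(n_nodes)))
  r
}

# independent naive PCIT oracle: literal triple loop over trios in R
naive_pcit <- function(r) {
  n <- nrow(r)
  sig <- matrix(TRUE, n, n)
  diag(sig) <- FALSE
  if (n < 3) return(sig)
  tiny <- 1e-12
  partial <- function(rab, rac, rbc) {
    den <- sqrt((1 - rac^2) * (1 - rbc^2))
    (rab - rac * rbc) / max(den, tiny)
  }
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
    pxy <- partial(rxy, rxz, ryz)
    pxz <- partial(rxz, rxy, ryz)
    pyz <- partial(ryz, rxy, rxz)
    ratios <- c()
    if (abs(rxy) >= tiny) ratios <- c(ratios, abs(pxy / rxy))
    if (abs(rxz) >= tiny) ratios <- c(ratios, abs(pxz / rxz))
    if (abs(ryz) >= tiny) ratios <- c(ratios, abs(pyz / ryz))
    if (length(ratios) == 0) next
    eps <- mean(ratios)
    if (abs(rxy) < abs(eps * rxz) && abs(rxy) < abs(eps * ryz)) {
      sig[x, y] <- sig[y, x] <- FALSE
    }
    if (abs(rxz) < abs(eps * rxy) && abs(rxz) < abs(eps * ryz)) {
      sig[x, z] <- sig[z, x] <- FALSE
    }
    if (abs(ryz) < abs(eps * rxy) && abs(ryz) < abs(eps * rxz)) {
      sig[y, z] <- sig[z, y] <- FALSE
    }
  }
  dimnames(sig) <- dimnames(r)
  sig
}

# build a co-association network directly from an edge list
make_network <- function(edges, tfs = character()) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = nodes))
  structure(
    list(
      edges = tibble::as_tibble(edges),
      nodes = tibble::tibble(gene = nodes, is_tf = nodes %in% tfs,
                             degree = as.integer(deg)),
      isolated = character(0), min_abs_r = 0
    ),
    class = "coassoc_network"
  )
}

# independent trio scorer using igraph neighborhoods
trio_scores_oracle <- function(net, tfs) {
  gr <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                      vertices = data.frame(name = net$nodes$gene))
  trios <- combn(sort(tfs), 3)
  scores <- integer(ncol(trios))
  for (i in seq_len(ncol(trios))) {
    trio <- trios[, i]
    nb <- unique(unlist(lapply(trio, function(v) {
      igraph::V(gr)$name[as.integer(igraph::neighbors(gr, v))]
    })))
    scores[i] <- length(setdiff(nb, trio))
  }
  list(trios = trios, scores = scores)
}

# brute-force SNP-to-gene overlap oracle
overlap_oracle <- function(snp_map, genes, flank) {
  rows <- list()
  for (i in seq_len(nrow(snp_map))) {
    for (j in seq_len(nrow(genes))) {
      if (snp_map$chr[i] == genes$chr[j] &&
          snp_map$pos[i] >= genes$start[j] - flank &&
          snp_map$pos[i] <= genes$end[j] + flank) {
        rows[[length(rows) + 1]] <- data.frame(
          snp = snp_map$snp[i], gene = genes$gene[j]
        )
      }
    }
  }
  if (length(rows) == 0) return(data.frame(snp = character(), gene = character()))
  do.call(rbind, rows)
}

# multi-trait association table with hand-controllable p/z values
fake_assoc <- function(snp_map, traits, p_mat, z_mat = NULL) {
  if (is.null(z_mat)) {
    z_mat <- sign(matrix(rnorm(length(p_mat)), nrow(p_mat))) *
      sqrt(qchisq(p_mat, 1, lower.tail = FALSE))
  }
  rows <- lapply(seq_along(traits), function(t) {
    tibble::tibble(
      snp = snp_map$snp, chr = snp_map$chr, pos = snp_map$pos,
      trait = traits[t], beta = z_mat[, t], se = 1,
      chi2 = z_mat[, t]^2, p_raw = p_mat[, t], p_gc = p_mat[, t],
      z_gc = z_mat[, t], maf = 0.2, snp_var = 0, pct_va = 0
    )
  })
  dplyr::bind_rows(rows)
}
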