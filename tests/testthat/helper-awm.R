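# Independent enumeration oracle for the AWM selection rules.
awm_oracle <- function(assoc, genes, key, p_key = 0.05, p_other = 0.05,
                       min_other = 3, dist_bp = 10000) {
  snps <- unique(assoc$snp)
  traits <- unique(assoc$trait)
  others <- setdiff(traits, key)
  get_p <- function(s, t) assoc$p_gc[assoc$snp == s & assoc$trait == t]
  get_z <- function(s, t) assoc$z_gc[assoc$snp == s & assoc$trait == t]
  rows <- list()
  for (s in snps) {
    meta <- assoc[assoc$snp == s, ][1, ]
    pk <- get_p(s, key)
    n_oth <- sum(vapply(others, function(t) get_p(s, t) < p_other, logical(1)))
    if (!(pk <= p_key || n_oth >= min_other)) next
    # nearest gene
    cand <- genes[genes$chr == meta$chr, ]
    if (nrow(cand) == 0) next
    d <- pmax(0, cand$start - meta$pos, meta$pos - cand$end)
    if (min(d) >= dist_bp) next
    ord <- order(d, cand$gene)
    rows[[s]] <- data.frame(
      snp = s, gene = cand$gene[ord[1]], chr = meta$chr, pos = meta$pos,
      p_key = pk, z_key = get_z(s, key)
    )
  }
  tab <- do.call(rbind, rows)
  # one SNP per gene
  kept <- lapply(split(tab, tab$gene), function(d) {
    d <- d[order(d$p_key, -abs(d$z_key), d$chr, d$pos), ]
    d[1, ]
  })
  kept <- do.call(rbind, kept)
  # Ap over key-associated SNPs at p <= p_key
  key_snps <- snps[vapply(snps, function(s) get_p(s, key) <= p_key, logical(1))]
  ap <- mean(vapply(key_snps, function(s) {
    sum(vapply(others, function(t) get_p(s, t) <= p_key, logical(1)))
  }, numeric(1)))
  list(genes = sort(kept$gene),
       snp_of = setNames(kept$snp, kept$gene), ap = ap)
}

make_awm_fixture <- function(seed = 99) {
  set.seed(seed)
  n_snp <- 100
  snp_map <- tibble::tibble(
    snp = sprintf("s%03d", 1:n_snp),
    chr = rep(1:2, each = n_snp / 2),
    pos = rep(seq(5000, by = 7000, length.out = n_snp / 2), 2)
  )
  genes <- tibble::tibble(
    gene = sprintf("G%02d", 1:30),
    chr = rep(1:2, each = 15),
    start = rep(seq(2000, by = 23000, length.out = 15), 2),
    end = rep(seq(2000, by = 23000, length.out = 15), 2) + 4000
  )
  traits <- sprintf("t%d", 1:6)
  p <- matrix(runif(n_snp * 6), n_snp)
  # engineered boundaries: key P exactly at threshold; far/near genes
  p[1, 1] <- 0.05          # inclusive key threshold
  p[2, 1] <- 0.050001      # just outside
  p[2, 2:5] <- 0.01        # but rescued by the >=3-other-traits clause
  p[3, ] <- 0.9            # passes nothing
  z <- sign(matrix(rnorm(n_snp * 6), n_snp)) *
    sqrt(qchisq(p, 1, lower.tail = FALSE))
  assoc <- fake_assoc(snp_map, traits, p, z)
  list(assoc = assoc, genes = genes, snp_map = snp_map)
}
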