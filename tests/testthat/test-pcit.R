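test_that("pairwise row correlations match hand computation", {
  z <- rbind(
    g1 = c(1, 2, 3, 4, 5),
    g2 = c(1, 2, 3, 4, 5),
    g3 = c(-1, -2, -3, -4, -5),
    g4 = c(2, 0, 4, 1, 3)
  )
  awm <- structure(list(matrix = z, key_trait = "t1"), class = "awm")
  r <- pairwise_correlation(awm)
  expect_equal(r["g1", "g2"], 1)
  expect_equal(r["g1", "g3"], -1)
  expect_equal(r["g1", "g4"], cor(z[1, ], z[4, ]))
  expect_equal(diag(r), setNames(rep(1, 4), rownames(z)))

  awm$matrix <- rbind(awm$matrix, g5 = rep(2, 5))
  expect_error(pairwise_correlation(awm), "g5")
})

test_that("the trio rule evaluates as stated on hand-built matrices", {
  # strong direct edge with two weak flankers: the lone trio cannot kill
  # any edge under the conjunctive rule (weak edges fail only one clause)
  r1 <- matrix(c(1, 0.9, 0.05,
                 0.9, 1, 0.05,
                 0.05, 0.05, 1), 3, 3)
  f1 <- pcit(r1)
  expect_true(f1[1, 2])
  expect_true(f1[1, 3])
  expect_true(f1[2, 3])

  # weak edge dominated by two strong indirect paths is removed:
  # r_xy = 0.3, r_xz = r_yz = 0.8 -> eps ~ 1.86, |r_xy| < eps*0.8 twice
  r2 <- matrix(c(1, 0.3, 0.8,
                 0.3, 1, 0.8,
                 0.8, 0.8, 1), 3, 3)
  f2 <- pcit(r2)
  expect_false(f2[1, 2])
  expect_true(f2[1, 3])
  expect_true(f2[2, 3])
  expect_identical(f2, naive_pcit(r2))
})

test_that("two-node and degenerate matrices pass vacuously", {
  r <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  f <- pcit(r)
  expect_true(f[1, 2])
  # equal off-diagonals: no trio can discriminate, all edges retained
  req <- matrix(0.6, 5, 5)
  diag(req) <- 1
  expect_true(all(pcit(req)[upper.tri(req)]))
  expect_error(pcit(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
  expect_error(pcit(matrix(1, 2, 3)), "square")
})

test_that("fast PCIT equals the naive oracle on random matrices", {
  set.seed(21)
  for (i in 1:10) {
    r <- random_corr(12)
    expect_identical(pcit(r), naive_pcit(r))
  }
})

test_that("PCIT is equivariant under node relabeling", {
  set.seed(22)
  r <- random_corr(10)
  f <- pcit(r)
  perm <- sample(10)
  f_perm <- pcit(r[perm, perm])
  expect_identical(unname(f_perm), unname(f[perm, perm]))
})

test_that("edge filtering applies the conjunction and boundary rules", {
  r <- matrix(0, 4, 4)
  rownames(r) <- colnames(r) <- c("a", "b", "c", "d")
  diag(r) <- 1
  r["a", "b"] <- r["b", "a"] <- 0.80    # boundary: retained (inclusive)
  r["a", "c"] <- r["c", "a"] <- -0.85   # negative: retained with sign
  r["b", "c"] <- r["c", "b"] <- 0.95    # significant flag forced off below
  r["a", "d"] <- r["d", "a"] <- 0.60    # below threshold
  flags <- matrix(TRUE, 4, 4, dimnames = dimnames(r))
  diag(flags) <- FALSE
  flags["b", "c"] <- flags["c", "b"] <- FALSE
  net <- filter_edges(r, flags, min_abs_r = 0.80, tf_catalog = "a")
  expect_identical(nrow(net$edges), 2L)
  expect_true(all(c("a|b", "a|c") %in% paste(net$edges$gene_a, net$edges$gene_b, sep = "|")))
  expect_equal(net$edges$weight[net$edges$gene_b == "c"], -0.85)
  expect_identical(net$isolated, "d")
  expect_true(net$nodes$is_tf[net$nodes$gene == "a"])
  # degree sum = 2 x edge count
  expect_identical(sum(net$nodes$degree), 2L * nrow(net$edges))
})

test_that("edge count is monotone non-increasing in the threshold", {
  set.seed(23)
  r <- random_corr(15)
  flags <- pcit(r)
  counts <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(th) {
    nrow(filter_edges(r, flags, min_abs_r = th)$edges)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lte(counts[1], sum(flags[upper.tri(flags)]))
})

test_that("topology metrics match hand enumeration on canonical graphs", {
  path <- make_network(tibble::tibble(
    gene_a = c("A", "B"), gene_b = c("B", "C"), weight = c(0.9, 0.9)
  ))
  tp <- topology(path)
  expect_identical(tp$degree[tp$gene == "B"], 2L)
  expect_equal(tp$betweenness[tp$gene == "B"], 1)
  expect_equal(tp$betweenness[tp$gene == "A"], 0)

  star <- make_network(tibble::tibble(
    gene_a = "hub", gene_b = sprintf("leaf%d", 1:4), weight = 0.9
  ))
  ts <- topology(star)
  expect_identical(ts$gene[which.max(ts$closeness)], "hub")
  expect_identical(ts$gene[which.max(ts$degree)], "hub")

  lonely <- make_network(tibble::tibble(
    gene_a = character(0), gene_b = character(0), weight = numeric(0)
  ))
  lonely$nodes <- tibble::tibble(gene = "solo", is_tf = FALSE, degree = 0L)
  tl <- topology(lonely)
  expect_identical(tl$degree, 0L)
  expect_equal(tl$closeness, 0)
  expect_equal(tl$betweenness, 0)
})

test_that("best trio maximises neighborhood coverage where greedy fails", {
  # TF A covers 6 targets spread over the blocks of B, C, D (3 each);
  # greedy picks A first and tops out at 8; the true optimum B+C+D covers 9
  edges <- tibble::tibble(
    gene_a = c(rep("A", 6), rep("B", 3), rep("C", 3), rep("D", 3)),
    gene_b = c("t1", "t2", "t4", "t5", "t7", "t8",
               "t1", "t2", "t3", "t4", "t5", "t6", "t7", "t8", "t9"),
    weight = 0.85
  )
  net <- make_network(edges, tfs = c("A", "B", "C", "D"))
  trio <- best_tf_trio(net)
  expect_setequal(trio$tf_ids, c("B", "C", "D"))
  expect_identical(trio$score, 9L)
  # greedy would have chosen A (6 direct targets) first
  greedy_first <- names(which.max(table(c(edges$gene_a))))
  expect_identical(greedy_first, "A")

  # exactly three TFs: forced trio
  net3 <- make_network(edges, tfs = c("A", "B", "C"))
  expect_setequal(best_tf_trio(net3)$tf_ids, c("A", "B", "C"))
  expect_error(best_tf_trio(make_network(edges, tfs = c("A", "B"))), "3 TFs")
})

test_that("trio selection equals exhaustive enumeration on random graphs", {
  set.seed(24)
  for (i in 1:5) {
    nodes <- sprintf("n%02d", 1:15)
    tfs <- sample(nodes, 5)
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.25
    edges <- tibble::tibble(
      gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
      weight = round(runif(sum(keep), -1, 1), 3)
    )
    edges <- edges[edges$weight != 0, ]
    net <- make_network(edges, tfs = tfs)
    tfs_in <- net$nodes$gene[net$nodes$is_tf]
    if (length(tfs_in) < 3) next
    trio <- best_tf_trio(net)
    oracle <- trio_scores_oracle(net, tfs_in)
    expect_identical(trio$score, as.integer(max(oracle$scores)))
  }
})

test_that("regulation classification counts signs per TF", {
  edges <- tibble::tibble(
    gene_a = c(rep("TF1", 3), rep("TF2", 13), rep("TF3", 2)),
    gene_b = c(sprintf("a%d", 1:3), sprintf("b%d", 1:13), c("c1", "c2")),
    weight = c(-0.9, -0.85, 0.81,
               rep(-0.82, 8), rep(0.9, 5),
               0.85, 0.9)
  )
  net <- make_network(edges, tfs = c("TF1", "TF2", "TF3"))
  trio <- best_tf_trio(net)
  reg <- classify_regulation(net, trio)
  expect_equal(reg$frac_repressed[reg$tf == "TF1"], 2 / 3)
  expect_equal(reg$frac_repressed[reg$tf == "TF2"], 8 / 13)
  expect_equal(reg$frac_repressed[reg$tf == "TF3"], 0)
  expect_equal(reg$frac_induced[reg$tf == "TF3"], 1)

  zero <- make_network(tibble::tibble(
    gene_a = c("TF1", "TF1", "TF2", "TF3", "TF2", "TF3"),
    gene_b = c("x1", "x2", "x2", "x3", "x4", "x5"),
    weight = c(0, 0.9, 0.8, -0.9, 0.8, 0.8)
  ), tfs = c("TF1", "TF2", "TF3"))
  trio0 <- best_tf_trio(zero)
  expect_warning(reg0 <- classify_regulation(zero, trio0), "zero-weight")
  expect_identical(reg0$n_targets[reg0$tf == "TF1"], 1L)
})

test_that("network exports are well-formed", {
  edges <- tibble::tibble(gene_a = c("a", "b"), gene_b = c("b", "c"),
                          weight = c(0.9, -0.85))
  net <- make_network(edges, tfs = "a")
  dir <- withr::local_tempdir()
  write_sif(net, file.path(dir, "net.sif"))
  expect_identical(readLines(file.path(dir, "net.sif")),
                   c("a\tr\tb", "b\tr\tc"))
  write_graphml(net, file.path(dir, "net.graphml"))
  gr <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::vcount(gr), 3)
  expect_equal(sort(igraph::E(gr)$weight), c(-0.85, 0.9))
})
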