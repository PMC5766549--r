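#' Pairwise gene-gene correlations of AWM rows
#'
#' Pearson correlation between the standardized-effect profiles (AWM rows)
#' of every gene pair. Genes whose profile is constant across traits have no
#' defined correlation and raise an error naming them.
#'
#' @param awm An [build_awm()] result with at least 3 traits.
#' @return Symmetric correlation matrix with unit diagonal, gene ids as
#'   dimnames.
#' @export
pairwise_correlation <- function(awm) {
  stopifnot(inherits(awm, "awm"))
  z <- awm$matrix
  if (ncol(z) < 3) abort("Need at least 3 traits for row correlations.")
  sds <- apply(z, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant AWM row for gene(s): ",
                 paste(head(rownames(z)[sds == 0], 5), collapse = ", ")))
  }
  r <- cor(t(z))
  diag(r) <- 1
  r
}

#' PCIT significance flags for a correlation matrix
#'
#' Partial Correlation and Information Theory filtering: for every unordered
#' node trio the three first-order partial correlations
#' \eqn{r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
#' \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}} are computed and the trio tolerance
#' \eqn{\epsilon} is the mean of the absolute partial/direct ratios (terms
#' with zero direct correlation are skipped). Edge (x, y) is locally
#' non-significant within the trio when \eqn{|r_{xy}| < |\epsilon r_{xz}|}
#' and \eqn{|r_{xy}| < |\epsilon r_{yz}|}; an edge survives globally iff no
#' trio renders it locally non-significant. With fewer than 3 nodes every
#' edge is significant vacuously.
#'
#' @param corr Square symmetric correlation matrix with unit diagonal.
#' @return Logical matrix of the same dimension: `TRUE` where the edge is
#'   significant (diagonal `FALSE`).
#' @export
pcit <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    abort("`corr` must be a square matrix.")
  }
  if (max(abs(corr - t(corr))) > 1e-8) abort("`corr` must be symmetric.")
  n <- nrow(corr)
  flags <- pcit_flags_cpp(corr)
  dimnames(flags) <- dimnames(corr)
  flags
}

#' Filter PCIT-significant edges by correlation magnitude
#'
#' Keeps edges that are PCIT-significant and have `|r| >= min_abs_r`
#' (inclusive). Nodes incident to at least one retained edge form the
#' network; genes that lose all their edges are reported as isolated.
#'
#' @param corr Correlation matrix (dimnames = gene ids).
#' @param flags [pcit()] output on the same matrix.
#' @param min_abs_r Absolute-correlation threshold (default 0.80).
#' @param tf_catalog Optional character vector of TF gene ids used to flag
#'   nodes.
#' @return Object of class `coassoc_network`: list with `edges` (tibble
#'   `gene_a`, `gene_b`, `weight`), `nodes` (tibble `gene`, `is_tf`,
#'   `degree`) and `isolated` (character vector).
#' @export
filter_edges <- function(corr, flags, min_abs_r = 0.80, tf_catalog = character()) {
  stopifnot(identical(dim(corr), dim(flags)))
  ids <- rownames(corr)
  if (is.null(ids)) ids <- sprintf("node%d", seq_len(nrow(corr)))
  keep <- flags & abs(corr) >= min_abs_r
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    gene_a = ids[idx[, 1]],
    gene_b = ids[idx[, 2]],
    weight = corr[idx]
  )
  edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  in_net <- sort(unique(c(edges$gene_a, edges$gene_b)))
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = in_net))
  nodes <- tibble::tibble(
    gene = in_net,
    is_tf = in_net %in% tf_catalog,
    degree = as.integer(deg)
  )
  structure(
    list(edges = edges, nodes = nodes, isolated = setdiff(ids, in_net),
         min_abs_r = min_abs_r),
    class = "coassoc_network"
  )
}

#' @export
print.coassoc_network <- function(x, ...) {
  cat(sprintf(
    "<coassoc_network> %d nodes (%d TFs), %d edges at |r| >= %.2f; %d isolated\n",
    nrow(x$nodes), sum(x$nodes$is_tf), nrow(x$edges), x$min_abs_r,
    length(x$isolated)
  ))
  invisible(x)
}

#' @export
tidy.coassoc_network <- function(x, ...) x$edges

# igraph view of a co-association network
.as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Topology metrics of a co-association network
#'
#' Unweighted shortest-path metrics: degree, closeness centrality computed
#' within each connected component, harmonic closeness over the whole graph
#' (the fallback that remains defined across components), and normalized
#' betweenness centrality. A single-node network yields zero centralities.
#'
#' @param net A [filter_edges()] network.
#' @return Tibble: `gene`, `is_tf`, `degree`, `component`, `closeness`,
#'   `harmonic_closeness`, `betweenness`, sorted by decreasing degree.
#' @export
topology <- function(net) {
  stopifnot(inherits(net, "coassoc_network"))
  if (nrow(net$nodes) == 0) {
    return(tibble::tibble(
      gene = character(), is_tf = logical(), degree = integer(),
      component = integer(), closeness = numeric(),
      harmonic_closeness = numeric(), betweenness = numeric()
    ))
  }
  gr <- .as_igraph(net)
  comp <- igraph::components(gr)
  clo <- rep(0, igraph::vcount(gr))
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(gr, members)
    clo[members] <- igraph::closeness(sub, normalized = TRUE, weights = NA)
  }
  btw <- if (igraph::vcount(gr) > 2) {
    igraph::betweenness(gr, directed = FALSE, normalized = TRUE, weights = NA)
  } else rep(0, igraph::vcount(gr))
  harm <- igraph::harmonic_centrality(gr, normalized = TRUE, weights = NA)
  out <- tibble::tibble(
    gene = igraph::V(gr)$name,
    is_tf = igraph::V(gr)$is_tf,
    degree = as.integer(igraph::degree(gr)),
    component = as.integer(comp$membership),
    closeness = as.numeric(clo),
    harmonic_closeness = as.numeric(harm),
    betweenness = as.numeric(btw)
  )
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$gene)
}

#' Best transcription-factor trio by direct-neighborhood coverage
#'
#' Exhaustively enumerates every triple of TF-flagged nodes and scores it by
#' the number of distinct network nodes in the union of the three direct
#' neighborhoods, excluding the trio members themselves ("information
#' lossless" coverage of the network topology). Ties are broken by the
#' larger summed absolute weight of the trio's incident edges, then by
#' lexicographic ids.
#'
#' @param net A [filter_edges()] network with at least 3 TF nodes.
#' @param tf_catalog Optional character vector overriding the network's TF
#'   flags.
#' @return Object of class `tf_trio`: list with `tf_ids` (3), `covered_targets`,
#'   `coverage_fraction` (covered / non-TF nodes), `score`, and `per_tf`
#'   (tibble `tf`, `n_targets`).
#' @export
best_tf_trio <- function(net, tf_catalog = NULL) {
  stopifnot(inherits(net, "coassoc_network"))
  tfs <- if (is.null(tf_catalog)) net$nodes$gene[net$nodes$is_tf] else
    intersect(net$nodes$gene, tf_catalog)
  tfs <- sort(tfs)
  if (length(tfs) < 3) {
    abort(sprintf("Need at least 3 TFs in the network, found %d.", length(tfs)))
  }
  nbrs <- .neighbor_list(net)
  wsum <- vapply(tfs, function(tf) {
    e <- net$edges
    sum(abs(e$weight[e$gene_a == tf | e$gene_b == tf]))
  }, numeric(1))
  trios <- combn(tfs, 3)
  best <- NULL
  for (i in seq_len(ncol(trios))) {
    trio <- trios[, i]
    covered <- setdiff(unique(c(nbrs[[trio[1]]], nbrs[[trio[2]]], nbrs[[trio[3]]])), trio)
    score <- length(covered)
    w <- sum(wsum[trio])
    if (is.null(best) || score > best$score ||
        (score == best$score && w > best$w + 1e-12) ||
        (score == best$score && abs(w - best$w) <= 1e-12 &&
         paste(trio, collapse = "\r") < paste(best$trio, collapse = "\r"))) {
      best <- list(trio = trio, covered = covered, score = score, w = w)
    }
  }
  non_tf <- setdiff(net$nodes$gene, tfs)
  per_tf <- tibble::tibble(
    tf = best$trio,
    n_targets = vapply(best$trio, function(tf) {
      length(setdiff(nbrs[[tf]], best$trio))
    }, integer(1))
  )
  structure(
    list(
      tf_ids = best$trio,
      covered_targets = sort(best$covered),
      coverage_fraction = if (length(non_tf) > 0) best$score / length(non_tf) else 0,
      score = best$score,
      per_tf = per_tf
    ),
    class = "tf_trio"
  )
}

.neighbor_list <- function(net) {
  nb <- setNames(vector("list", nrow(net$nodes)), net$nodes$gene)
  for (g in names(nb)) nb[[g]] <- character(0)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[i]
    b <- net$edges$gene_b[i]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

#' @export
print.tf_trio <- function(x, ...) {
  cat(sprintf(
    "<tf_trio> %s: %d covered targets (%.1f%% of non-TF nodes)\n",
    paste(x$tf_ids, collapse = ", "), x$score, 100 * x$coverage_fraction
  ))
  invisible(x)
}

#' Classify trio targets as induced or repressed
#'
#' A target of a trio TF counts as repressed when the TF-target edge weight
#' is negative and induced when positive; zero-weight edges are excluded
#' with a warning.
#'
#' @param net A [filter_edges()] network.
#' @param trio A [best_tf_trio()] result.
#' @return Tibble: `tf`, `n_targets`, `n_induced`, `n_repressed`,
#'   `frac_induced`, `frac_repressed`.
#' @export
classify_regulation <- function(net, trio) {
  stopifnot(inherits(net, "coassoc_network"), inherits(trio, "tf_trio"))
  e <- net$edges
  rows <- lapply(trio$tf_ids, function(tf) {
    inc <- e[e$gene_a == tf | e$gene_b == tf, , drop = FALSE]
    partner <- ifelse(inc$gene_a == tf, inc$gene_b, inc$gene_a)
    ok <- !partner %in% trio$tf_ids
    inc <- inc[ok, , drop = FALSE]
    if (any(inc$weight == 0)) {
      warn(sprintf("Excluding %d zero-weight edge(s) of %s.",
                   sum(inc$weight == 0), tf))
      inc <- inc[inc$weight != 0, , drop = FALSE]
    }
    n_ind <- sum(inc$weight > 0)
    n_rep <- sum(inc$weight < 0)
    n <- n_ind + n_rep
    tibble::tibble(
      tf = tf, n_targets = n, n_induced = n_ind, n_repressed = n_rep,
      frac_induced = if (n > 0) n_ind / n else NA_real_,
      frac_repressed = if (n > 0) n_rep / n else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Export a network as SIF
#'
#' Simple interaction format: `gene_a<TAB>r<TAB>gene_b`, one edge per line.
#'
#' @param net A [filter_edges()] network.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "coassoc_network"))
  lines <- sprintf("%s\tr\t%s", net$edges$gene_a, net$edges$gene_b)
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as GraphML with weight and TF attributes
#'
#' @param net A [filter_edges()] network.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "coassoc_network"))
  gr <- .as_igraph(net)
  igraph::E(gr)$sign <- ifelse(net$edges$weight >= 0, "positive", "negative")
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}
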