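#' Map SNPs to genes by proximity
#'
#' Assigns each SNP to every gene whose interval, extended by `flank_bp` on
#' both sides, contains its position (1-based inclusive coordinates; a SNP
#' exactly `flank_bp` beyond a gene end is assigned). Multi-assignment to
#' overlapping genes is allowed. SNPs on chromosomes absent from the
#' annotation are left unassigned and counted in the attribute
#' `n_unassigned`.
#'
#' @param snp_map Tibble with `snp`, `chr`, `pos`.
#' @param genes Tibble with `gene`, `chr`, `start`, `end` (1-based
#'   inclusive).
#' @param flank_bp Flanking distance in bp (default 15000).
#' @return Tibble with columns `snp`, `gene`, `distance` (0 inside the gene,
#'   else bp to the nearest end); attribute `n_unassigned`.
#' @export
map_snps_to_genes <- function(snp_map, genes, flank_bp = 15000) {
  if (flank_bp < 0) abort("`flank_bp` must be non-negative.")
  hits <- dplyr::inner_join(
    dplyr::select(snp_map, "snp", "chr", "pos"),
    dplyr::select(genes, "gene", "chr", "start", "end"),
    by = "chr", relationship = "many-to-many"
  )
  hits <- dplyr::filter(hits, .data$pos >= .data$start - flank_bp,
                        .data$pos <= .data$end + flank_bp)
  hits <- dplyr::mutate(
    hits,
    distance = pmax(0, .data$start - .data$pos, .data$pos - .data$end)
  )
  out <- dplyr::select(hits, "snp", "gene", "distance")
  attr(out, "n_unassigned") <- length(setdiff(snp_map$snp, out$snp))
  attr(out, "flank_bp") <- flank_bp
  out
}

#' Trait-wise significant gene sets
#'
#' A gene is significant for a trait when any SNP assigned to it reaches
#' `p_gc < alpha` in the association scan (nominal threshold; the gene-set
#' stage deliberately uses a laxer cut than the genome-wide scan so that
#' weak but coordinated signals can accumulate).
#'
#' @param assoc An [grammar_scan()]/[gwas_scan()] tibble (any tibble with
#'   `snp`, `trait`, `p_gc`).
#' @param assignment A [map_snps_to_genes()] result.
#' @param alpha Per-SNP significance level (default 0.05, strict `<`).
#' @return Tibble with columns `trait`, `gene`.
#' @export
significant_genes <- function(assoc, assignment, alpha = 0.05) {
  sig <- dplyr::filter(assoc, !is.na(.data$p_gc), .data$p_gc < alpha)
  out <- dplyr::inner_join(
    dplyr::select(sig, "snp", "trait"),
    dplyr::select(assignment, "snp", "gene"),
    by = "snp", relationship = "many-to-many"
  )
  dplyr::distinct(dplyr::select(out, "trait", "gene"))
}

#' Fisher over-representation test for gene-set categories
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) of
#' over-representation of significant genes in each category, after
#' intersecting categories with the gene universe and keeping only
#' categories with more than `min_size` and fewer than `max_size` genes
#' (both bounds strict). Benjamini-Hochberg q-values are computed over
#' exactly the retained categories.
#'
#' @param sig_genes Character vector of significant gene ids (subset of
#'   `universe`).
#' @param universe Character vector: all testable genes (typically every
#'   gene with at least one assigned SNP).
#' @param gene_sets Named list of gene-id vectors.
#' @param min_size,max_size Strict size bounds on category size after
#'   intersection with the universe (defaults: keep sizes in (10, 1000)).
#' @return Tibble of class `enrichment_result`: `category`, `n_category`,
#'   `n_significant_in_category`, `odds_direction`, `p_fisher`, `q_value`,
#'   sorted by P; attribute `adjust_method = "BH"`.
#' @export
fisher_enrichment <- function(sig_genes, universe, gene_sets,
                              min_size = 10, max_size = 1000) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("Empty gene universe.")
  sig_genes <- intersect(unique(sig_genes), universe)
  n_univ <- length(universe)
  n_sig <- length(sig_genes)
  sets <- lapply(gene_sets, intersect, universe)
  sizes <- lengths(sets)
  keep <- sizes > min_size & sizes < max_size
  sets <- sets[keep]
  if (length(sets) == 0) {
    out <- tibble::tibble(
      category = character(), n_category = integer(),
      n_significant_in_category = integer(), odds_direction = character(),
      p_fisher = numeric(), q_value = numeric()
    )
  } else {
    rows <- purrr::map2_dfr(names(sets), sets, function(nm, members) {
      k <- length(intersect(sig_genes, members))
      m <- length(members)
      tab <- matrix(c(k, n_sig - k, m - k, n_univ - n_sig - (m - k)), 2, 2)
      p <- fisher.test(tab, alternative = "greater")$p.value
      expected <- n_sig * m / n_univ
      tibble::tibble(
        category = nm, n_category = m, n_significant_in_category = k,
        odds_direction = if (k >= expected) "over" else "under",
        p_fisher = p
      )
    })
    rows$q_value <- p.adjust(rows$p_fisher, method = "BH")
    out <- dplyr::arrange(rows, .data$p_fisher)
  }
  class(out) <- c("enrichment_result", class(out))
  attr(out, "adjust_method") <- "BH"
  attr(out, "n_universe") <- n_univ
  attr(out, "n_significant") <- n_sig
  out
}
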