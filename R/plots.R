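#' Manhattan plot of an association scan
#'
#' @param object An `assoc_scan` tibble.
#' @param threshold Genome-wide significance line on `p_gc` (default 5e-5).
#' @param ... Unused.
#' @return A ggplot object, faceted by trait when several are present.
#' @export
autoplot.assoc_scan <- function(object, threshold = 5e-5, ...) {
  df <- dplyr::filter(object, !is.na(.data$p_gc))
  df <- dplyr::mutate(df, chr_parity = factor(.data$chr %% 2))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pos, y = -log10(.data$p_gc), colour = .data$chr_parity
  )) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold),
                        colour = "red", linetype = 2) +
    ggplot2::facet_grid(trait ~ chr, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](italic(P)[GC]))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  p
}

#' Null distribution of the variance-explained permutation test
#'
#' @param object A `permutation_report`.
#' @param ... Unused.
#' @return A ggplot object: histogram of the null variance fractions with
#'   the observed value marked.
#' @export
autoplot.permutation_report <- function(object, ...) {
  df <- tibble::tibble(null = object$null_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_var_fraction,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(
      x = "variance fraction explained by random SNP sets",
      y = "replicates",
      title = sprintf("observed = %.3f, null mean = %.3f (P %s)",
                      object$observed_var_fraction, object$null_mean,
                      object$p_label)
    ) +
    ggplot2::theme_minimal()
}

#' Enrichment results bar chart
#'
#' @param object An `enrichment_result`.
#' @param q_cut Highlight categories below this q-value (default 0.05).
#' @param ... Unused.
#' @return A ggplot object of -log10 q per category.
#' @export
autoplot.enrichment_result <- function(object, q_cut = 0.05, ...) {
  df <- dplyr::mutate(object,
                      significant = .data$q_value < q_cut,
                      category = stats::reorder(.data$category, -.data$q_value))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$category, y = -log10(.data$q_value), fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(q_cut), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(q)))) +
    ggplot2::theme_minimal()
}

#' Trait correlation heatmap from AWM columns
#'
#' @param object A `trait_clustering`.
#' @param ... Unused.
#' @return A ggplot tile map of the trait-trait correlations, ordered by the
#'   dendrogram.
#' @export
autoplot.trait_clustering <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  df <- tibble::as_tibble(object$correlation, rownames = "trait_a")
  df <- tidyr::pivot_longer(df, -"trait_a", names_to = "trait_b",
                            values_to = "r")
  df$trait_a <- factor(df$trait_a, levels = ord)
  df$trait_b <- factor(df$trait_b, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$trait_a, .data$trait_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
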