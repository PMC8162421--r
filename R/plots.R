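#' Heatmap of top marker genes
#'
#' Tile plot of log2 fold-changes for the genes returned by
#' [top_markers()], genes ordered by their attributed group.
#'
#' @param fp a [compute_footprint()] result.
#' @param markers a [top_markers()] table (default: computed from `fp`).
#' @return A ggplot object.
#' @export
plot_marker_heatmap <- function(fp, markers = top_markers(fp)) {
  long <- tidy(fp) |>
    dplyr::filter(.data$gene %in% markers$gene) |>
    dplyr::mutate(gene = factor(.data$gene, levels = rev(markers$gene)))
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$gene,
                                     fill = log2(.data$fc))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", name = "log2 FC") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Volcano-style plot of a Fisher DE result
#'
#' @param de a [fisher_de()] result.
#' @return A ggplot object: log2 enrichment against -log10 adjusted p,
#'   significant genes highlighted.
#' @export
plot_de <- function(de) {
  stopifnot(inherits(de, "de_result"))
  ggplot2::ggplot(de, ggplot2::aes(.data$log2_enrichment,
                                   -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "seagreen")) +
    ggplot2::labs(x = "log2 enrichment", y = "-log10 adjusted p") +
    ggplot2::theme_classic()
}

#' Symbiont occupancy barplot
#'
#' @param occ an [occupancy()] table.
#' @return A ggplot object: fraction of symbiont-positive cells per
#'   metacell.
#' @export
plot_occupancy <- function(occ) {
  ggplot2::ggplot(occ, ggplot2::aes(.data$metacell, .data$fraction)) +
    ggplot2::geom_col(fill = "darkolivegreen4") +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x)
      paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "symbiont-positive cells") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Cross-species divergence heatmap with top links
#'
#' @param kld a [kld_matrix()] result.
#' @param links optional [top_links()] table to mark.
#' @return A ggplot object.
#' @export
plot_kld <- function(kld, links = NULL) {
  long <- tibble::as_tibble(as.table(kld), .name_repair = "minimal") |>
    stats::setNames(c("celltype_a", "celltype_b", "divergence"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$celltype_b, .data$celltype_a,
                                          fill = .data$divergence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "KLD (bits)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(links) && nrow(links)) {
    p <- p + ggplot2::geom_point(
      data = links, ggplot2::aes(.data$celltype_b, .data$celltype_a),
      inherit.aes = FALSE, shape = 21, size = 3, colour = "black",
      fill = NA)
  }
  p
}

#' Gene-age distribution plot
#'
#' @param ages a [dollo_age()] table.
#' @param sets optional named list of gene sets to overlay as proportions.
#' @return A ggplot object of stratum proportions.
#' @export
plot_age_distribution <- function(ages, sets = NULL) {
  base <- ages |>
    dplyr::count(.data$stratum) |>
    dplyr::mutate(prop = .data$n / sum(.data$n), set = "all genes")
  df <- if (is.null(sets)) base else dplyr::bind_rows(
    base,
    purrr::imap_dfr(sets, function(g, nm) {
      ages |>
        dplyr::filter(.data$gene %in% g) |>
        dplyr::count(.data$stratum) |>
        dplyr::mutate(prop = .data$n / sum(.data$n), set = nm)
    }))
  ggplot2::ggplot(df, ggplot2::aes(.data$stratum, .data$prop,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "phylostratum", y = "fraction of genes", fill = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
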