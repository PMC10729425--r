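#' Plot fragment-length distributions
#'
#' One line per sample; the nucleosome-free mode and the mono/di
#' nucleosomal modes near 180 and 360 bp are the qualitative QC targets.
#'
#' @param hist Tibble from [fragment_length_histogram()].
#' @param max_len Right edge of the plotted range (bp).
#' @return A ggplot object.
#' @export
plot_fragment_lengths <- function(hist, max_len = 800L) {
  hist |>
    filter(.data$bin_start <= max_len) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$bin_start, y = .data$count,
                                 colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' Plot a TSS insertion profile
#' @param profile A `tss_profile`.
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile) {
  tidy(profile) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$position,
                                 y = .data$mean_signal)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "insertions per gene per bp") +
    ggplot2::theme_minimal()
}

#' Plot the replicate correlation matrix in dendrogram order
#' @param clust A `ths_clustergram`.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(clust) {
  ord <- colnames(clust$correlation)[clust$order]
  tidy(clust) |>
    mutate(sample_a = factor(.data$sample_a, levels = ord),
           sample_b = factor(.data$sample_b, levels = ord)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                 fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the SOM label lattice
#' @param object A `som_stage_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.som_stage_model <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$x, y = .data$y,
                                 colour = .data$stage,
                                 size = .data$n_mapped)) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "SOM node labels", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the bipartite ATAC-RNA network
#'
#' ATAC nodes on the left, RNA nodes on the right, edges between them.
#'
#' @param object A `ths_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ths_network <- function(object, ...) {
  genes <- sort(unique(object$nodes$gene_id))
  layout <- object$nodes |>
    mutate(x = if_else(.data$source == "ATAC", 0, 1),
           y = match(.data$gene_id, genes))
  seg <- object$edges |>
    mutate(y0 = match(.data$atac_gene, genes),
           y1 = match(.data$rna_gene, genes))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = 0, xend = 1, y = .data$y0,
                                       yend = .data$y1),
                          alpha = 0.4, colour = "grey50") +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$source)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "assay") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
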