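#' Plot a clustered PPI network
#'
#' Draws the network with a deterministic Fruchterman-Reingold layout and
#' colours nodes by their complex role, mirroring the usual grey
#' (outlier) / yellow (overlap) / red (cluster) scheme.
#'
#' @param object A `ppi_clustering`.
#' @param g The PPI network the clustering was computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_clustering
#' @export
autoplot.ppi_clustering <- function(object, g, ...) {
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- net_nodes(g)
  lay <- tibble(gene_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  lay <- left_join(lay, object$roles, by = "gene_id")
  e <- net_edges(g)
  seg <- tibble(x = lay$x[match(e$id_a, lay$gene_id)],
                y = lay$y[match(e$id_a, lay$gene_id)],
                xend = lay$x[match(e$id_b, lay$gene_id)],
                yend = lay$y[match(e$id_b, lay$gene_id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$role), size = 2) +
    ggplot2::scale_colour_manual(values = c(cluster = "#c0392b",
                                            overlap = "#f1c40f",
                                            outlier = "grey55")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "role", title = object$label)
}

#' Bar chart of the most enriched GO terms
#'
#' @param object A `ppi_enrichment`.
#' @param n Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_enrichment
#' @export
autoplot.ppi_enrichment <- function(object, n = 15, ...) {
  top <- slice_head(as_tibble(object), n = n)
  top$name <- factor(top$name, levels = rev(top$name))
  ggplot2::ggplot(top, ggplot2::aes(x = -log10(.data$p_value),
                                    y = .data$name,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2980b9",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' Degree distribution with hubs highlighted
#'
#' @param g A PPI network.
#' @param k Number of top hubs to highlight (default 10).
#' @return A ggplot object.
#' @export
plot_hub_degrees <- function(g, k = 10) {
  hubs <- top_hubs(g, k = k)
  deg <- tibble(gene_id = igraph::V(g)$name,
                degree = as.integer(igraph::degree(g)))
  deg$hub <- deg$gene_id %in% hubs$gene_id
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$degree, fill = .data$hub)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "degree", y = "nodes", fill = "top hub") +
    ggplot2::theme_minimal()
}
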