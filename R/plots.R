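#' Volcano plot of a differential-expression table
#'
#' @param de A [call_de()] table.
#' @return A ggplot object: log2FC against -log10 adjusted p, colored by
#'   call direction, with the cutoffs drawn as dashed lines.
#' @export
plot_volcano <- function(de) {
  cuts <- attr(de, "cutoffs") %||% c(lfc_cut = 1, padj_cut = 0.05)
  ggplot2::ggplot(as_tibble(de),
                  ggplot2::aes(x = .data$log2FC,
                               y = -log10(.data$padj),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * cuts[["lfc_cut"]],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(cuts[["padj_cut"]]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#4575b4",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cerna_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  g <- as_igraph(object)
  lay <- withr::with_seed(1, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- lay[, 1]
  nodes$y <- lay[, 2]
  edges <- object$edges |>
    left_join(dplyr::select(nodes, id, xa = "x", ya = "y"),
              by = c(id_a = "id")) |>
    left_join(dplyr::select(nodes, id, xb = "x", yb = "y"),
              by = c(id_b = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linetype = .data$edge_type),
      colour = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$rna_type,
                   shape = .data$direction),
      size = 2.5
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "RNA type", shape = "direction",
                  linetype = "edge type")
}

#' @export
autoplot.gsea_es <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$running_sum)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_rug(data = dplyr::filter(d, .data$hit),
                      sides = "b", colour = "grey30", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank", y = "running enrichment score",
                  title = object$set_name) +
    ggplot2::theme_minimal()
}
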