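#' Plot a co-occurrence network
#'
#' Circular layout with taxa on the rim; solid links are positive
#' associations, dashed links negative, the usual convention for signed
#' co-occurrence diagrams.
#'
#' @param object A `pn_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pn_network
#' @export
autoplot.pn_network <- function(object, ...) {
  g <- object$graph
  s <- igraph::vcount(g)
  theta <- seq(0, 2 * pi, length.out = s + 1)[seq_len(s)]
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          x = cos(theta), y = sin(theta),
                          degree = igraph::degree(g))
  ed <- tidy(object)
  ed$x <- nodes$x[match(ed$taxon_a, nodes$name)]
  ed$y <- nodes$y[match(ed$taxon_a, nodes$name)]
  ed$xend <- nodes$x[match(ed$taxon_b, nodes$name)]
  ed$yend <- nodes$y[match(ed$taxon_b, nodes$name)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend,
                   linetype = factor(.data$sign, c(1, -1),
                                     c("positive", "negative")),
                   linewidth = abs(.data$rho)),
      colour = "grey40", alpha = 0.7, show.legend = c(linewidth = FALSE)
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, size = .data$degree),
                        colour = "steelblue") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x * 1.12, .data$y * 1.12,
                                    label = .data$name), size = 2.6) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2)) +
    ggplot2::labs(linetype = "association",
                  title = object$label %||% NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a CONISS dendrogram's split diagnostics
#'
#' Observed dispersion explained by each successive split against the
#' broken-stick expectation; splits above the broken-stick line support an
#' additional zone.
#'
#' @param object A `pn_coniss` tree.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pn_coniss
#' @export
autoplot.pn_coniss <- function(object, ...) {
  bs <- broken_stick(object)$table
  long <- tidyr::pivot_longer(bs, c("observed", "expected"),
                              names_to = "series", values_to = "dispersion")
  ggplot2::ggplot(long, ggplot2::aes(.data$split, .data$dispersion,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "split number", y = "dispersion explained",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplots of null-ensemble metrics by group
#'
#' The replicate distribution of each network metric across the
#' constrained random ensembles, one panel per metric — the usual way to
#' display whether metrics shifted between periods or zones.
#'
#' @param object A `pn_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pn_comparison
#' @export
autoplot.pn_comparison <- function(object, ...) {
  metrics <- intersect(c("connectance", "modularity", "mean_degree",
                         "skewness"), names(object$ensemble))
  long <- tidyr::pivot_longer(object$ensemble, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$label, .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "null-ensemble value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
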