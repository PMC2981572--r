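#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enrichment map
#'
#' @param x An `enrichment_map`.
#' @param what `"nodes"` (default) or `"edges"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy enrichment_map
#' @export
tidy.enrichment_map <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' One-row summary of an enrichment map
#'
#' @param x An `enrichment_map`.
#' @param ... Unused.
#' @return A one-row tibble: node/edge counts, per-dataset significant
#'   counts, metric, cutoff and thresholds.
#' @method glance enrichment_map
#' @export
glance.enrichment_map <- function(x, ...) {
  md <- x$metadata
  out <- tibble::tibble(
    n_nodes = sum(x$nodes$role == "geneset"),
    n_edges = sum(x$edges$role == "similarity"),
    n_signature_nodes = sum(x$nodes$role == "signature"),
    n_signature_edges = sum(x$edges$role == "signature"),
    n_datasets = length(md$datasets),
    metric = md$metric,
    cutoff = md$cutoff,
    p_max = md$p_max,
    q_max = md$q_max,
    n_unresolved = md$n_unresolved
  )
  for (d in seq_along(md$datasets)) {
    out[[paste0("n_significant", d)]] <-
      sum(x$nodes[[paste0("significant", d)]], na.rm = TRUE)
  }
  out
}

#' Plot an enrichment map
#'
#' Renders the laid-out map with ggplot2: edges as segments whose linewidth
#' encodes the similarity coefficient (pink for signature edges), nodes as
#' points sized by gene-set size and filled with the diverging
#' red/white/blue gradient of the first dataset's colour score (triangles
#' for signature nodes).
#'
#' @param object A styled, laid-out `enrichment_map`.
#' @param label_nodes Add set_id text labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_map
#' @export
autoplot.enrichment_map <- function(object, label_nodes = FALSE, ...) {
  nodes <- object$nodes
  if (anyNA(nodes$x)) {
    stop("map has no coordinates; run layout_map() first", call. = FALSE)
  }
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, "set_id", xa = "x", ya = "y"),
                     by = c(a = "set_id")) |>
    dplyr::left_join(dplyr::select(nodes, "set_id", xb = "x", yb = "y"),
                     by = c(b = "set_id"))
  p <- ggplot2::ggplot()
  sim <- edges[edges$role == "similarity", ]
  if (nrow(sim) > 0) {
    p <- p + ggplot2::geom_segment(
      data = sim,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$coefficient),
      colour = "grey60"
    )
  }
  sig <- edges[edges$role == "signature", ]
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_segment(
      data = sig,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$width),
      colour = "pink"
    )
  }
  p <- p +
    ggplot2::geom_point(
      data = nodes[nodes$role == "geneset", ],
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                   fill = .data$color_score1),
      shape = 21
    ) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = "enrichment") +
    ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none") +
    ggplot2::scale_size(range = c(2, 8), name = "set size") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  tri <- nodes[nodes$role == "signature", ]
  if (nrow(tri) > 0) {
    p <- p + ggplot2::geom_point(
      data = tri,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size),
      shape = 24, fill = "yellow"
    )
  }
  if (label_nodes) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$set_id),
      vjust = -1, size = 3
    )
  }
  p
}

#' Plot heat-map data for a gene-set
#'
#' @param hm A tibble from [heatmap_data()].
#' @param ... Unused.
#' @return A ggplot tile plot, genes in score order, samples grouped by
#'   class.
#' @export
plot_heatmap <- function(hm, ...) {
  long <- tidyr::pivot_longer(hm, -"gene", names_to = "sample",
                              values_to = "value")
  long$gene <- factor(long$gene, levels = rev(hm$gene))
  long$sample <- factor(long$sample, levels = names(attr(hm, "classes")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "black",
                                  high = "yellow", name = "expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
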