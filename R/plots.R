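#' Plot threshold-sweep trajectories
#'
#' Shows how the network evolves as the edge-weight threshold rises:
#' modularity, node/edge counts, component structure and triangle census,
#' one facet per metric, with the selected `tau_star` marked.
#'
#' @param object an `epi_sweep`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.epi_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$grid, -"tau",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = object$tau_star, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(tau ~ "(edge-weight threshold)"), y = NULL,
                  title = "Threshold sweep",
                  subtitle = paste0("tau* = ", format(object$tau_star))) +
    ggplot2::theme_minimal()
}

#' Heatmap of directional community similarity
#'
#' Normalized-AUC similarity of every community pair, one panel per
#' direction. Asymmetry between panels is expected: the score is normalized
#' by the source community's size.
#'
#' @param object an `epi_similarity`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.epi_similarity <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = factor(.data$community_b),
                               y = factor(.data$community_a),
                               fill = .data$auc_norm)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "norm. AUC") +
    ggplot2::labs(x = "target community", y = "source community",
                  title = "Directional community similarity") +
    ggplot2::theme_minimal()
}

#' Plot an epistatic network
#'
#' Force-directed layout with nodes coloured by community when a partition
#' is supplied; edge transparency follows evidence strength (smaller
#' adjusted p = more opaque).
#'
#' @param object an `epi_network`.
#' @param partition optional `epi_partition` for node colours.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.epi_network <- function(object, partition = NULL, ...) {
  g <- as_igraph(object)
  set.seed(1L)  # layout only; analysis results never depend on this
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1L], y = xy[, 2L])
  if (!is.null(partition)) {
    nodes <- dplyr::left_join(nodes, partition$membership[c("snp", "community")],
                              by = "snp")
    nodes$community <- factor(nodes$community)
  }
  ed <- object$edges |>
    dplyr::left_join(dplyr::rename(nodes[c("snp", "x", "y")],
                                   xa = "x", ya = "y"),
                     by = c(snp_a = "snp")) |>
    dplyr::left_join(dplyr::rename(nodes[c("snp", "x", "y")],
                                   xb = "x", yb = "y"),
                     by = c(snp_b = "snp"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       alpha = 1 - .data$weight),
                          colour = "grey50", show.legend = FALSE)
  if (is.null(partition)) {
    p <- p + ggplot2::geom_point(data = nodes,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 colour = "#2c7fb8", size = 2)
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$community),
      size = 2)
  }
  p + ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Epistatic network (tau = ",
                                 format(object$tau), ")"))
}
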