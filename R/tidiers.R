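#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()` returns
#' the per-element table (edges, node assignments, grid rows, scores),
#' `glance()` a one-row summary.
#'
#' @param x a package result object.
#' @param ... unused.
#' @return a tibble.
#' @name episnet-tidiers
NULL

#' @rdname episnet-tidiers
#' @export
tidy.epi_network <- function(x, ...) {
  dplyr::mutate(x$edges, tau = x$tau)
}

#' @rdname episnet-tidiers
#' @export
glance.epi_network <- function(x, ...) {
  dplyr::mutate(network_metrics(x), tau = x$tau, .before = 1L)
}

#' @rdname episnet-tidiers
#' @export
tidy.epi_partition <- function(x, ...) x$membership

#' @rdname episnet-tidiers
#' @export
glance.epi_partition <- function(x, ...) {
  tibble::tibble(n_communities = x$n_communities,
                 modularity = x$modularity,
                 gamma = x$gamma,
                 largest_community = max(table(x$membership$community)))
}

#' @rdname episnet-tidiers
#' @export
tidy.epi_sweep <- function(x, ...) x$grid

#' @rdname episnet-tidiers
#' @export
glance.epi_sweep <- function(x, ...) {
  at <- x$grid[x$grid$tau == x$tau_star, ][1L, ]
  tibble::tibble(tau_star = x$tau_star,
                 max_modularity = at$modularity,
                 n_nodes = at$n_nodes,
                 n_edges = at$n_edges,
                 n_triangles = at$n_triangles,
                 tau_triangle_onset = x$tau_triangle_onset,
                 gamma = x$gamma,
                 step = x$step)
}

#' @rdname episnet-tidiers
#' @export
tidy.epi_similarity <- function(x, ...) x$scores

#' @rdname episnet-tidiers
#' @export
glance.epi_similarity <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$scores),
    mean_auc_norm = mean(x$scores$auc_norm),
    max_auc_norm = max(x$scores$auc_norm)
  )
}
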