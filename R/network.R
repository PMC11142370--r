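#' Build an epistatic network at an edge-weight threshold
#'
#' An epistatic network `N = {V, E, tau}` contains an edge for every tested
#' pair whose weight (FDR-adjusted interaction p-value) is less than or equal
#' to `tau`; nodes are exactly the endpoints of surviving edges, so the
#' network carries no isolated SNPs. Duplicate unordered pairs are collapsed
#' keeping the smallest weight.
#'
#' @param pairs an `epi_pairs` tibble from [pairwise_scan()] or any data
#'   frame with columns `snp_a`, `snp_b` and a weight column (`p_adj`, else
#'   `weight`). SNP ids must parse via [parse_snp_id()].
#' @param tau edge-weight threshold (>= 0); inclusive (`weight <= tau`).
#' @return an `epi_network`: list with `nodes` (tibble `snp`, `chrom`,
#'   `pos`), `edges` (tibble `snp_a`, `snp_b`, `weight`) and `tau`.
#' @export
build_network <- function(pairs, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop("tau must be a single non-negative number", call. = FALSE)
  }
  ed <- canonical_edges(pairs)
  # relative slack only: grid arithmetic (e.g. 434 * 1e-4) and file-parsed
  # weights may differ in the last ulp, but tau = 0 must admit only weight 0
  keep <- ed$weight <= tau * (1 + 1e-9)
  new_epi_network(ed[keep, , drop = FALSE], tau)
}

# normalize a pair table: parse ids, order endpoints, collapse duplicates
canonical_edges <- function(pairs, warn_dupes = FALSE) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0L) stop("pair list is empty", call. = FALSE)
  stopifnot(all(c("snp_a", "snp_b") %in% names(pairs)))
  w <- if ("p_adj" %in% names(pairs)) pairs$p_adj else pairs$weight
  if (is.null(w)) stop("pair table needs a 'p_adj' or 'weight' column", call. = FALSE)
  a <- parse_snp_id(pairs$snp_a)
  b <- parse_snp_id(pairs$snp_b)
  if (any(a$chrom == b$chrom & a$pos == b$pos)) {
    stop("self-pair (identical loci) in pair table", call. = FALSE)
  }
  swap <- locus_before(b$chrom, b$pos, a$chrom, a$pos)
  ed <- tibble::tibble(
    snp_a = ifelse(swap, b$snp, a$snp),
    snp_b = ifelse(swap, a$snp, b$snp),
    chrom_a = ifelse(swap, b$chrom, a$chrom),
    pos_a = ifelse(swap, b$pos, a$pos),
    chrom_b = ifelse(swap, a$chrom, b$chrom),
    pos_b = ifelse(swap, a$pos, b$pos),
    weight = as.numeric(w)
  )
  key <- paste(ed$snp_a, ed$snp_b)
  if (anyDuplicated(key)) {
    if (warn_dupes) {
      warning(sum(duplicated(key)), " duplicate pair(s) collapsed to the ",
              "smallest weight", call. = FALSE)
    }
    ed <- ed |>
      dplyr::group_by(.data$snp_a, .data$snp_b) |>
      dplyr::slice_min(.data$weight, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  dplyr::arrange(ed, .data$chrom_a, .data$pos_a, .data$chrom_b, .data$pos_b)
}

new_epi_network <- function(edges, tau) {
  nodes <- tibble::tibble(
    snp = c(edges$snp_a, edges$snp_b),
    chrom = c(edges$chrom_a, edges$chrom_b),
    pos = c(edges$pos_a, edges$pos_b)
  )
  nodes <- dplyr::distinct(nodes) |> dplyr::arrange(.data$chrom, .data$pos)
  structure(list(
    nodes = nodes,
    edges = edges[c("snp_a", "snp_b", "weight")],
    tau = tau
  ), class = "epi_network")
}

#' @export
print.epi_network <- function(x, ...) {
  cat("<epi_network> tau = ", format(x$tau), ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Convert an epistatic network to an igraph object
#'
#' Vertices carry `chrom` and `pos` attributes; edges carry `weight`
#' (the FDR-adjusted p-value, smaller = stronger evidence).
#'
#' @param net an `epi_network`.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "epi_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Topological metrics of an epistatic network
#'
#' Connected components, the size and node fraction of the largest component,
#' and the number of undirected triangle motifs (each unordered node triple
#' with all three edges present counted once).
#'
#' @param net an `epi_network`.
#' @return one-row tibble: `n_nodes`, `n_edges`, `n_components`,
#'   `largest_component_size`, `largest_component_ratio`, `n_triangles`.
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "epi_network"))
  if (nrow(net$edges) == 0L) {
    return(tibble::tibble(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                          largest_component_size = 0L,
                          largest_component_ratio = 0,
                          n_triangles = 0L))
  }
  g <- as_igraph(net)
  comp <- igraph::components(g)
  largest <- max(comp$csize)
  tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_components = comp$no,
    largest_component_size = as.integer(largest),
    largest_component_ratio = largest / igraph::vcount(g),
    n_triangles = as.integer(sum(igraph::count_triangles(g)) / 3L)
  )
}

# edges as integer endpoint indices into net$nodes (locus-sorted)
edge_indices <- function(net) {
  cbind(match(net$edges$snp_a, net$nodes$snp),
        match(net$edges$snp_b, net$nodes$snp))
}

#' Network modularity
#'
#' Evaluates \deqn{Q = \frac{1}{2m} \sum_{ij} \left[A_{ij} -
#' \gamma\frac{k_i k_j}{2m}\right]\delta(c_i, c_j)} over all ordered node
#' pairs of the (unweighted) network adjacency, where `m` is the edge count,
#' `k_i` the node degree, and the delta selects same-community pairs. The
#' resolution `gamma` trades intra- against inter-community edges; the
#' pipeline default is 1.
#'
#' @param net an `epi_network` with at least one edge.
#' @param membership community assignment: a tibble with columns `snp` and
#'   `community`, or a vector named by SNP id. Must cover every network node.
#' @param gamma resolution parameter (default 1).
#' @return modularity Q (a number in `[-1, 1]`).
#' @export
modularity_q <- function(net, membership, gamma = 1) {
  stopifnot(inherits(net, "epi_network"))
  if (nrow(net$edges) == 0L) stop("network has no edges", call. = FALSE)
  comm <- membership_vector(membership, net$nodes$snp)
  ei <- edge_indices(net)
  m <- nrow(ei)
  deg <- tabulate(c(ei[, 1L], ei[, 2L]), nbins = nrow(net$nodes))
  # per-community identity: sum_c [E_c/m - gamma (d_c / 2m)^2]
  intra <- comm[ei[, 1L]] == comm[ei[, 2L]]
  e_c <- tapply(rep(1L, m)[intra], comm[ei[intra, 1L]], sum)
  d_c <- tapply(deg, comm, sum)
  q <- sum(e_c) / m - gamma * sum((d_c / (2 * m))^2)
  as.numeric(q)
}

membership_vector <- function(membership, snps) {
  if (is.data.frame(membership)) {
    stopifnot(all(c("snp", "community") %in% names(membership)))
    v <- stats::setNames(membership$community, membership$snp)
  } else {
    v <- membership
  }
  if (is.null(names(v))) stop("membership must be named by SNP id", call. = FALSE)
  miss <- setdiff(snps, names(v))
  if (length(miss)) {
    stop("membership missing for node(s): ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  out <- v[snps]
  # contiguous integer codes in order of first appearance
  match(out, unique(out))
}

#' Greedy modularity community detection
#'
#' Agglomerative (Clauset-Newman-Moore style) maximization: every node starts
#' in its own community; at each step the merge of two edge-connected
#' communities yielding the largest modularity increase is applied; the
#' procedure stops when no merge increases Q. Merges tied on \eqn{\Delta Q}
#' are resolved by the lexicographically smallest community-id pair (ids
#' follow locus order), making the result deterministic.
#'
#' @param net an `epi_network` with at least one edge.
#' @param gamma resolution parameter.
#' @return an `epi_partition`: list with `membership` (tibble `snp`, `chrom`,
#'   `pos`, `community`), `modularity`, `gamma` and `n_communities`.
#'   Community ids are contiguous from 0 in order of decreasing size (ties by
#'   smallest member locus).
#' @export
detect_communities <- function(net, gamma = 1) {
  stopifnot(inherits(net, "epi_network"))
  if (nrow(net$edges) == 0L) stop("network has no edges", call. = FALSE)
  ei <- edge_indices(net)
  n <- nrow(net$nodes)
  m <- nrow(ei)
  comm <- seq_len(n)
  deg <- tabulate(c(ei[, 1L], ei[, 2L]), nbins = n)
  d <- as.numeric(deg)          # community degree sums
  B <- matrix(0, n, n)          # inter-community edge counts
  for (t in seq_len(m)) {
    i <- ei[t, 1L]; j <- ei[t, 2L]
    B[i, j] <- B[i, j] + 1
    B[j, i] <- B[j, i] + 1
  }
  active <- rep(TRUE, n)
  repeat {
    # Delta Q of merging communities c, d sharing B[c,d] edges:
    #   B[c,d]/m - gamma * d_c * d_d / (2 m^2)
    dq <- B / m - gamma * outer(d, d) / (2 * m^2)
    dq[B == 0] <- -Inf
    dq[!active, ] <- -Inf
    dq[, !active] <- -Inf
    dq[lower.tri(dq, diag = TRUE)] <- -Inf
    best <- max(dq)
    if (!is.finite(best) || best <= 1e-14) break
    cand <- which(dq >= best - 1e-14, arr.ind = TRUE)
    # lexicographically smallest (row, col) pair among ties
    pick <- cand[order(cand[, 1L], cand[, 2L])[1L], ]
    c1 <- pick[[1L]]; c2 <- pick[[2L]]
    d[c1] <- d[c1] + d[c2]
    B[c1, ] <- B[c1, ] + B[c2, ]
    B[, c1] <- B[, c1] + B[, c2]
    B[c1, c1] <- 0
    active[c2] <- FALSE
    B[c2, ] <- 0; B[, c2] <- 0
    comm[comm == c2] <- c1
  }
  # relabel 0..k-1 by decreasing size, ties by smallest member (locus order)
  sizes <- table(comm)
  first_member <- tapply(seq_len(n), comm, min)
  lvl <- names(sizes)[order(-as.integer(sizes), as.integer(first_member))]
  community <- match(as.character(comm), lvl) - 1L
  membership <- dplyr::bind_cols(net$nodes, tibble::tibble(community = community))
  q <- modularity_q(net, stats::setNames(community, net$nodes$snp), gamma)
  structure(list(membership = membership, modularity = q, gamma = gamma,
                 n_communities = length(lvl)),
            class = "epi_partition")
}

#' @export
print.epi_partition <- function(x, ...) {
  cat("<epi_partition> ", x$n_communities, " communities, Q = ",
      format(x$modularity, digits = 4), " (gamma = ", x$gamma, ")\n", sep = "")
  invisible(x)
}

#' Sweep the edge-weight threshold and select the modularity optimum
#'
#' Starting from `tau = 0` the threshold is raised in increments of `step`
#' (default 0.0001) up to the first grid point at or above the largest edge
#' weight, so the final network contains every input pair. At each grid point
#' the thresholded network's metrics and greedy-modularity Q are recorded
#' (Q = 0 for an edge-free network). `tau_star` is the smallest grid point
#' attaining the maximum Q — the sparser network is preferred on ties — and
#' `tau_triangle_onset` is the smallest grid point at which triangles appear.
#'
#' @param pairs pair table as for [build_network()].
#' @param step grid increment (> 0).
#' @param gamma modularity resolution.
#' @return an `epi_sweep`: list with `grid` (tibble of `tau`, the
#'   [network_metrics()] columns and `modularity`), `tau_star`,
#'   `tau_triangle_onset` (`NA` if no triangles ever form), `gamma`, `step`.
#' @export
sweep_threshold <- function(pairs, step = 1e-4, gamma = 1) {
  stopifnot(step > 0)
  ed <- canonical_edges(pairs)
  ed <- ed[order(ed$weight), , drop = FALSE]
  k_max <- ceiling(max(ed$weight) / step - 1e-9)
  grid <- step * (0:max(k_max, 0L))
  n_at <- findInterval(grid * (1 + 1e-9), ed$weight)  # edges admitted per tau
  rows <- vector("list", length(grid))
  last_n <- -1L
  last_row <- NULL
  last_q <- NA_real_
  for (g in seq_along(grid)) {
    k <- n_at[g]
    if (k == last_n) {
      rows[[g]] <- dplyr::mutate(last_row, tau = grid[g], .before = 1L)
      next
    }
    net <- new_epi_network(ed[seq_len(k), , drop = FALSE][c(
      "snp_a", "snp_b", "chrom_a", "pos_a", "chrom_b", "pos_b", "weight")],
      tau = grid[g])
    met <- network_metrics(net)
    q <- if (k == 0L) 0 else detect_communities(net, gamma)$modularity
    last_row <- dplyr::mutate(met, modularity = q)
    last_n <- k
    rows[[g]] <- dplyr::mutate(last_row, tau = grid[g], .before = 1L)
  }
  grid_tbl <- dplyr::bind_rows(rows)
  tau_star <- grid_tbl$tau[which.max(grid_tbl$modularity)]
  onset <- grid_tbl$tau[grid_tbl$n_triangles > 0]
  structure(list(
    grid = grid_tbl,
    tau_star = tau_star,
    tau_triangle_onset = if (length(onset)) onset[1L] else NA_real_,
    gamma = gamma,
    step = step
  ), class = "epi_sweep")
}

#' @export
print.epi_sweep <- function(x, ...) {
  cat("<epi_sweep> ", nrow(x$grid), " grid points (step ", format(x$step),
      "), tau* = ", format(x$tau_star), ", max Q = ",
      format(max(x$grid$modularity), digits = 4), "\n", sep = "")
  invisible(x)
}
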