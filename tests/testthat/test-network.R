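test_that("thresholding is inclusive and collapses duplicates to min weight", {
  pairs <- tibble::tibble(
    snp_a = c("chr1.10", "chr1.10", "chr1.20", "chr2.10"),
    snp_b = c("chr1.20", "chr1.20", "chr2.10", "chr1.10"),
    p_adj = c(0.02, 0.01, 0.05, 0.03))
  # duplicate (1.10, 1.20) keeps 0.01; (2.10, 1.10) reorders endpoints and
  # duplicates (1.20, 2.10)? no - different pair, kept
  net <- build_network(pairs, tau = 0.05)
  expect_identical(nrow(net$edges), 3L)
  w <- net$edges$weight[net$edges$snp_a == "chr1.10" &
                          net$edges$snp_b == "chr1.20"]
  expect_equal(w, 0.01)
  # saturating threshold admits all, sub-minimum admits none
  expect_identical(nrow(build_network(pairs, tau = 1)$edges), 3L)
  empty <- build_network(pairs, tau = 0.001)
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(nrow(empty$nodes), 0L)
  # boundary: weight == tau is included
  expect_identical(nrow(build_network(pairs, tau = 0.01)$edges), 1L)
  expect_error(build_network(pairs, tau = -0.1), "non-negative")
})

test_that("network metrics match hand counts on canonical graphs", {
  two_tri <- net_from_edges(two_triangles_edges())
  m <- network_metrics(two_tri)
  expect_equal(m$n_nodes, 6)
  expect_equal(m$n_edges, 6)
  expect_equal(m$n_components, 2)
  expect_equal(m$largest_component_ratio, 0.5)
  expect_identical(m$n_triangles, 2L)

  k4 <- net_from_edges(t(utils::combn(4, 2)))
  expect_identical(network_metrics(k4)$n_triangles, 4L)

  path5 <- net_from_edges(cbind(1:4, 2:5))
  mp <- network_metrics(path5)
  expect_identical(mp$n_triangles, 0L)
  expect_equal(mp$n_components, 1)
})

test_that("triangle counts agree with brute-force triple enumeration", {
  set.seed(30)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    all_pairs <- t(utils::combn(n, 2))
    edges <- all_pairs[runif(nrow(all_pairs)) < 0.15, , drop = FALSE]
    if (nrow(edges) == 0) next
    net <- net_from_edges(edges)
    expect_identical(network_metrics(net)$n_triangles,
                     brute_triangle_count(net))
  }
})

test_that("modularity engine reproduces hand-derived values", {
  two_tri <- net_from_edges(two_triangles_edges())
  nodes <- two_tri$nodes$snp
  one_comm <- stats::setNames(rep(1L, 6), nodes)
  expect_equal(modularity_q(two_tri, one_comm), 0, tolerance = 1e-12)
  # the two cycles: 2 x (3/6 - (6/12)^2) = 0.5
  cycles <- stats::setNames(rep(1:2, each = 3), nodes)
  expect_equal(modularity_q(two_tri, cycles), 0.5, tolerance = 1e-12)
  # single edge, endpoints split: Q = -0.5
  one_edge <- net_from_edges(rbind(c(1, 2)))
  split2 <- stats::setNames(1:2, one_edge$nodes$snp)
  expect_equal(modularity_q(one_edge, split2), -0.5, tolerance = 1e-12)
  expect_error(modularity_q(two_tri, one_comm[-1]), "missing")
})

test_that("per-community modularity equals the literal double sum", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(5:12, 1)
    all_pairs <- t(utils::combn(n, 2))
    edges <- all_pairs[runif(nrow(all_pairs)) < 0.4, , drop = FALSE]
    if (nrow(edges) == 0) next
    net <- net_from_edges(edges)
    nn <- nrow(net$nodes)
    comm <- sample(1:3, nn, replace = TRUE)
    gamma <- sample(c(0.5, 1, 1.5), 1)
    expect_equal(modularity_q(net, stats::setNames(comm, net$nodes$snp), gamma),
                 brute_modularity(net, comm, gamma), tolerance = 1e-12)
  }
})

test_that("modularity agrees with the igraph implementation", {
  set.seed(32)
  net <- net_from_edges(bridged_cliques_edges(4))
  g <- as_igraph(net)
  comm <- sample(1:2, nrow(net$nodes), replace = TRUE)
  expect_equal(
    modularity_q(net, stats::setNames(comm, net$nodes$snp)),
    igraph::modularity(g, comm),
    tolerance = 1e-12)
})

test_that("greedy detection finds the exhaustive optimum on small fixtures", {
  fixtures <- list(
    two_triangles = net_from_edges(two_triangles_edges()),
    bridged_cliques = net_from_edges(bridged_cliques_edges(4)),
    single_triangle = net_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3))),
    path4 = net_from_edges(cbind(1:3, 2:4))
  )
  for (nm in names(fixtures)) {
    net <- fixtures[[nm]]
    part <- detect_communities(net)
    best <- brute_best_partition(net)
    expect_lte(part$modularity, best$q + 1e-12)
    if (nm %in% c("two_triangles", "bridged_cliques", "single_triangle")) {
      expect_equal(part$modularity, best$q, tolerance = 1e-12)
    }
  }
  # two disjoint 3-cycles resolve into the two cycles at Q = 0.5
  part <- detect_communities(fixtures$two_triangles)
  expect_identical(part$n_communities, 2L)
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  split_by_comm <- split(part$membership$snp, part$membership$community)
  expect_setequal(split_by_comm[[1]], net_from_edges(two_triangles_edges())$nodes$snp[1:3])
  # one triangle stays a single community at Q = 0
  p1 <- detect_communities(fixtures$single_triangle)
  expect_identical(p1$n_communities, 1L)
  expect_equal(p1$modularity, 0, tolerance = 1e-12)
  # bridged 4-cliques split into the cliques
  pb <- detect_communities(fixtures$bridged_cliques)
  expect_identical(pb$n_communities, 2L)
  sizes <- table(pb$membership$community)
  expect_true(all(sizes == 4))
})

test_that("reported modularity re-evaluates identically on the assignment", {
  set.seed(33)
  all_pairs <- t(utils::combn(15, 2))
  edges <- all_pairs[runif(nrow(all_pairs)) < 0.2, , drop = FALSE]
  net <- net_from_edges(edges)
  part <- detect_communities(net)
  expect_equal(part$modularity,
               modularity_q(net, part$membership[c("snp", "community")]),
               tolerance = 1e-12)
  # community ids contiguous from 0, ordered by descending size
  sizes <- as.integer(table(part$membership$community))
  expect_identical(sort(unique(part$membership$community)),
                   seq_along(sizes) - 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("greedy result is deterministic across calls", {
  net <- net_from_edges(bridged_cliques_edges(3))
  p1 <- detect_communities(net)
  p2 <- detect_communities(net)
  expect_identical(p1$membership, p2$membership)
})

test_that("threshold sweep tracks monotone growth and picks the optimum", {
  # two planted 5-node communities, intra-community weights <= 0.01,
  # bridges at 0.04: the optimum threshold excludes the bridges
  clique <- function(v) t(utils::combn(v, 2))
  intra <- rbind(clique(1:5), clique(6:10))
  bridges <- rbind(c(5, 6), c(1, 10))
  set.seed(34)
  pairs <- tibble::tibble(
    snp_a = paste0("chr1.", c(intra[, 1], bridges[, 1]) * 10),
    snp_b = paste0("chr1.", c(intra[, 2], bridges[, 2]) * 10),
    p_adj = c(runif(nrow(intra), 0.001, 0.01), rep(0.04, 2)))
  sw <- sweep_threshold(pairs, step = 1e-3)
  expect_lt(glance(sw)$tau_star, 0.04)
  g <- sw$grid
  expect_true(all(diff(g$n_edges) >= 0))
  expect_true(all(diff(g$n_nodes) >= 0))
  expect_true(all(diff(g$n_triangles) >= 0))
  expect_true(all(diff(g$tau) > 0))
  # grid ends at the first point at or above the max weight
  expect_gte(max(g$tau), 0.04)
  expect_lt(max(g$tau) - 1e-3, 0.04)
  # the sweep's Q at tau_star matches a fresh build + detect
  at <- g[g$tau == sw$tau_star, ]
  fresh <- detect_communities(build_network(pairs, sw$tau_star))
  expect_equal(at$modularity, fresh$modularity, tolerance = 1e-12)
  # triangle onset: smallest tau with a complete triangle
  expect_true(g$n_triangles[g$tau == sw$tau_triangle_onset][1] > 0)

  # single pair: Q = 0 on the whole grid, tau_star = 0 by smallest-tau tie-break
  sw1 <- sweep_threshold(tibble::tibble(snp_a = "chr1.10", snp_b = "chr1.20",
                                        p_adj = 0.01), step = 1e-3)
  expect_true(all(sw1$grid$modularity == 0))
  expect_equal(sw1$tau_star, 0)
})
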