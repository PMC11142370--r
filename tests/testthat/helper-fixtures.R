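# Fixture builders and independent brute-force oracles. Oracles deliberately
# avoid the package's own code paths: literal formula evaluation, exhaustive
# enumeration, and stats::lm refits.

# network from integer edge pairs; node i sits at chr1 position i * 10
net_from_edges <- function(edges, weight = 0.01, chrom = "1", step_bp = 10) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  w <- rep_len(weight, nrow(edges))
  id <- function(i) paste0("chr", chrom, ".", i * step_bp)
  pairs <- tibble::tibble(snp_a = id(edges[, 1L]), snp_b = id(edges[, 2L]),
                          p_adj = w)
  build_network(pairs, tau = max(w))
}

two_triangles_edges <- function() rbind(c(1, 2), c(2, 3), c(1, 3),
                                        c(4, 5), c(5, 6), c(4, 6))

bridged_cliques_edges <- function(k = 4L) {
  clique <- function(v) t(utils::combn(v, 2L))
  rbind(clique(1:k), clique((k + 1):(2 * k)), c(k, k + 1L))
}

# literal double-sum modularity: Q = (1/2m) sum_ij [A_ij - g k_i k_j / 2m] d(c_i,c_j)
brute_modularity <- function(net, comm, gamma = 1) {
  n <- nrow(net$nodes)
  A <- matrix(0, n, n)
  ia <- match(net$edges$snp_a, net$nodes$snp)
  ib <- match(net$edges$snp_b, net$nodes$snp)
  for (t in seq_along(ia)) {
    A[ia[t], ib[t]] <- 1
    A[ib[t], ia[t]] <- 1
  }
  m <- length(ia)
  k <- rowSums(A)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (comm[i] == comm[j]) s <- s + A[i, j] - gamma * k[i] * k[j] / (2 * m)
    }
  }
  s / (2 * m)
}

# all set partitions of 1..n as restricted growth strings (n <= 8 -> 4140)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(code, k) {
    i <- length(code) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- code
      return(invisible())
    }
    for (c in seq_len(k + 1L)) recurse(c(code, c), max(k, c))
  }
  recurse(integer(), 0L)
  out
}

# exhaustive modularity optimum over every partition of the network's nodes
brute_best_partition <- function(net, gamma = 1) {
  parts <- all_partitions(nrow(net$nodes))
  qs <- vapply(parts, function(p) brute_modularity(net, p, gamma), numeric(1L))
  best <- which.max(qs)
  list(q = qs[best], comm = parts[[best]])
}

# brute-force triangle census over all node triples
brute_triangle_count <- function(net) {
  n <- nrow(net$nodes)
  if (n < 3L) return(0L)
  key <- paste(net$edges$snp_a, net$edges$snp_b)
  has_edge <- function(a, b) {
    paste(a, b) %in% key || paste(b, a) %in% key
  }
  ids <- net$nodes$snp
  count <- 0L
  for (trio in utils::combn(n, 3L, simplify = FALSE)) {
    a <- ids[trio[1L]]; b <- ids[trio[2L]]; c <- ids[trio[3L]]
    if (has_edge(a, b) && has_edge(a, c) && has_edge(b, c)) count <- count + 1L
  }
  count
}

# quadratic all-pairs tolerance matching on loci tables
brute_node_matches <- function(a, b, delta) {
  hits <- 0L
  for (i in seq_len(nrow(a))) {
    found <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && abs(a$pos[i] - b$pos[j]) <= delta) {
        found <- TRUE
        break
      }
    }
    if (found) hits <- hits + 1L
  }
  hits
}

# stats::lm refit oracle for the interaction p-value
lm_interaction_p <- function(y, g1, g2, code_fun) {
  fit <- stats::lm(y ~ g1 + g2 + code, data = data.frame(y = y, g1 = g1,
                                                         g2 = g2,
                                                         code = code_fun(g1, g2)))
  stats::coef(summary(fit))["code", "Pr(>|t|)"]
}

# quick planted-pair dataset for scan tests
planted_xor_data <- function(seed, n = 200L, n_snps = 12L, beta = 1.2,
                             noise_sd = 1, maf = 0.5,
                             pair = c(2L, n_snps - 3L)) {
  loci <- snp_loci(n_snps, n_chrom = 3L, seed = 1000L + seed)
  G <- simulate_genotypes(n, loci, maf = maf, seed = seed)
  arch <- epi_architecture(pairs = data.frame(a = pair[1L], b = pair[2L],
                                              model = "xor", beta = beta),
                           noise_sd = noise_sd)
  y <- simulate_phenotype(G, arch, seed = seed + 5e5L)
  list(G = G, y = y, planted = sort(colnames(G$codes)[pair]))
}
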