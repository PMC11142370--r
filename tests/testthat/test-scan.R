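test_that("BH adjustment reproduces the hand-computed step-up", {
  # min over j >= i of m * p_(j) / j: (3*.01/1, 3*.02/2, 3*.03/3) -> all 0.03
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)                  # m = 1: identity
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))  # ties unchanged
  expect_error(bh_adjust(c(0.1, 1.5)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
  # monotone on sorted input, never above 1
  set.seed(1)
  p <- sort(runif(50))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj) >= -1e-12))
  expect_true(all(adj <= 1))
})

test_that("MAF filter prunes inclusively on the empirical frequency", {
  loci <- snp_loci(3, seed = 4)
  codes <- cbind(rep(0L, 100),                      # monomorphic
                 c(rep(1L, 10), rep(0L, 90)),       # maf = 0.05 exactly
                 c(rep(1L, 40), rep(0L, 60)))       # maf = 0.20
  colnames(codes) <- loci$snp
  G <- episnet:::new_geno_matrix(codes, loci)
  expect_identical(ncol(maf_filter(G, 0)$codes), 3L)       # identity at 0
  kept <- maf_filter(G, 0.05)
  expect_identical(colnames(kept$codes), loci$snp[2:3])    # boundary inclusive
  expect_warning(maf_filter(G, 0.3), "no loci")
  expect_error(maf_filter(G, 0.5), "min_maf")
})

test_that("interaction test agrees with a stats::lm refit and is symmetric", {
  set.seed(10)
  for (enc in c("xor", "cartesian")) {
    code_fun <- if (enc == "xor") encode_xor else encode_cartesian
    g1 <- sample(0:2, 80, replace = TRUE)
    g2 <- sample(0:2, 80, replace = TRUE)
    y <- rnorm(80) + 0.5 * code_fun(g1, g2)
    mine <- interaction_test(y, g1, g2, enc)
    expect_false(mine$degenerate)
    expect_equal(mine$p_raw, lm_interaction_p(y, g1, g2, code_fun),
                 tolerance = 1e-10)
    flipped <- interaction_test(y, g2, g1, enc)
    expect_equal(mine$p_raw, flipped$p_raw, tolerance = 1e-10)
  }
})

test_that("degenerate designs are flagged, not fatal", {
  set.seed(11)
  y <- rnorm(50)
  g <- sample(0:2, 50, replace = TRUE)
  const <- rep(1L, 50)
  r <- interaction_test(y, g, const, "cartesian")
  expect_true(r$degenerate)
  expect_equal(r$p_raw, 1)
  r3 <- threeway_test(y, g, g, const, "xor")  # aliased + constant
  expect_true(r3$degenerate)
  # too few complete observations
  r_small <- interaction_test(rnorm(5), sample(0:2, 5, TRUE),
                              sample(0:2, 5, TRUE), "xor")
  expect_true(r_small$degenerate)
})

test_that("pairwise scan matches a brute-force lm loop on few SNPs", {
  set.seed(12)
  loci <- snp_loci(6, n_chrom = 2, seed = 12)
  G <- simulate_genotypes(120, loci, maf = 0.4, seed = 13)
  y <- simulate_phenotype(G, epi_architecture(
    pairs = data.frame(a = 1, b = 4, model = "xor", beta = 1)), seed = 14)
  scan <- pairwise_scan(G, y, "xor", min_maf = 0)

  combos <- utils::combn(6, 2)
  oracle <- purrr::map_dfr(seq_len(ncol(combos)), function(t) {
    i <- combos[1, t]; j <- combos[2, t]
    tibble::tibble(
      snp_a = colnames(G$codes)[i], snp_b = colnames(G$codes)[j],
      p_raw = lm_interaction_p(y$phenotype, G$codes[, i], G$codes[, j],
                               encode_xor))
  })
  oracle$p_adj <- stats::p.adjust(oracle$p_raw, "BH")
  merged <- dplyr::inner_join(scan, oracle, by = c("snp_a", "snp_b"),
                              suffix = c("", "_oracle"))
  expect_identical(nrow(merged), ncol(combos))
  expect_equal(merged$p_raw, merged$p_raw_oracle, tolerance = 1e-9)
  expect_equal(merged$p_adj, merged$p_adj_oracle, tolerance = 1e-9)
  # deterministic ordering by adjusted p then locus key
  expect_true(all(diff(scan$p_adj) >= -1e-15))
})

test_that("two-SNP scan reduces to a single unadjusted test", {
  loci <- snp_loci(2, seed = 15)
  G <- simulate_genotypes(60, loci, maf = 0.4, seed = 16)
  y <- simulate_phenotype(G, seed = 17)
  scan <- pairwise_scan(G, y, "cartesian", min_maf = 0)
  expect_identical(nrow(scan), 1L)
  expect_equal(scan$p_adj, scan$p_raw)
})

test_that("null scans stay quiet and planted scans recover the pair", {
  # null: no significant pair after FDR
  loci <- snp_loci(20, n_chrom = 4, seed = 18)
  G <- simulate_genotypes(300, loci, maf = 0.4, seed = 18)
  y_null <- simulate_phenotype(G, seed = 19)
  scan_null <- pairwise_scan(G, y_null, "xor", min_maf = 0)
  expect_identical(sum(scan_null$significant), 0L)

  # planted XOR pair is the top hit and the only significant one
  d <- planted_xor_data(seed = 21, beta = 1.5)
  scan <- pairwise_scan(d$G, d$y, "xor", min_maf = 0)
  expect_identical(sort(c(scan$snp_a[1], scan$snp_b[1])), d$planted)
  expect_true(scan$significant[1])
  expect_identical(sum(scan$significant), 1L)
})

test_that("xor-encoded scan outpowers cartesian on a planted XOR pair", {
  wins <- vapply(1:30, function(s) {
    d <- planted_xor_data(seed = 300 + s, n = 150, n_snps = 8, beta = 1)
    p_at_planted <- function(enc) {
      scan <- pairwise_scan(d$G, d$y, enc, min_maf = 0)
      key <- paste(scan$snp_a, scan$snp_b)
      scan$p_adj[key == paste(d$planted[1], d$planted[2])]
    }
    p_at_planted("xor") < p_at_planted("cartesian")
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("three-way test detects a planted parity effect beyond pairwise terms", {
  loci <- snp_loci(3, seed = 23)
  G <- simulate_genotypes(300, loci, maf = 0.5, seed = 23)
  arch <- epi_architecture(triples = data.frame(a = 1, b = 2, c = 3,
                                                model = "xor", beta = 1.5))
  y <- simulate_phenotype(G, arch, seed = 24)
  r <- threeway_test(y, G$codes[, 1], G$codes[, 2], G$codes[, 3], "xor")
  expect_lt(r$p_raw, 1e-6)
  # no three-way effect under a purely pairwise architecture
  arch2 <- epi_architecture(pairs = data.frame(a = 1, b = 2, model = "xor",
                                               beta = 1.5))
  y2 <- simulate_phenotype(G, arch2, seed = 25)
  r2 <- threeway_test(y2, G$codes[, 1], G$codes[, 2], G$codes[, 3], "xor")
  expect_gt(r2$p_raw, 0.001)
})
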