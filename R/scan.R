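#' Benjamini-Hochberg FDR adjustment
#'
#' Thin validated wrapper over the step-up procedure (`stats::p.adjust`,
#' method `"BH"`); adjusted values are returned in input order. Pairwise and
#' three-way scans are each adjusted across their own full family of tests.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Filter loci on empirical minor-allele frequency
#'
#' Loci are pruned before scanning: a column is retained when its empirical
#' minor-allele frequency (computed over non-missing genotypes) is at least
#' `min_maf`. The boundary is inclusive and column order is preserved.
#'
#' @param G a `geno_matrix`.
#' @param min_maf threshold in `[0, 0.5)`; default 0.05.
#' @return a filtered `geno_matrix`.
#' @export
maf_filter <- function(G, min_maf = 0.05) {
  stopifnot(inherits(G, "geno_matrix"))
  if (min_maf < 0 || min_maf >= 0.5) {
    stop("min_maf must lie in [0, 0.5)", call. = FALSE)
  }
  freq <- colMeans(G$codes, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  keep <- !is.na(maf) & maf >= min_maf
  if (!any(keep)) {
    warning("no loci pass the MAF filter", call. = FALSE)
  }
  new_geno_matrix(G$codes[, keep, drop = FALSE], G$loci[keep, , drop = FALSE])
}

# OLS two-sided p-value for the last column of X, with degeneracy detection.
# Returns c(p, degenerate). Rank deficiency (constant or aliased columns),
# too few complete observations, or a perfect fit all yield p = 1 + flag.
ols_last_p <- function(X, y) {
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- nrow(X)
  k <- ncol(X)
  if (n < 10L || n <= k) return(c(1, 1))
  q <- qr(X)
  if (q$rank < k) return(c(1, 1))
  coef <- qr.coef(q, y)
  res <- y - X %*% coef
  df <- n - k
  sigma2 <- sum(res^2) / df
  if (sigma2 < .Machine$double.eps * stats::var(y) * n) return(c(1, 1))
  xtx_inv <- matrix(NA_real_, k, k)
  xtx_inv[q$pivot, q$pivot] <- chol2inv(qr.R(q))
  tval <- unname(coef[k]) / sqrt(sigma2 * xtx_inv[k, k])
  c(2 * stats::pt(-abs(tval), df), 0)
}

#' Test a single pair of loci for epistatic interaction
#'
#' Fits the linear model `y ~ intercept + g1 + g2 + code(g1, g2)` by ordinary
#' least squares on pairwise-complete individuals and returns the two-sided
#' t-test p-value for the interaction coefficient. The encoding determines
#' the interaction code: multiplicative product (`"cartesian"`) or
#' heterozygosity parity (`"xor"`); a custom code function of two genotype
#' vectors may be supplied. Constant columns, rank-deficient designs or too
#' few complete observations are reported as degenerate with p = 1, not as
#' errors, so whole-genome scans are never interrupted.
#'
#' @param y phenotype (numeric vector or tibble with a `phenotype` column).
#' @param g1,g2 genotype columns (codes 0/1/2, `NA` = missing).
#' @param encoding `"xor"`, `"cartesian"`, or a function `(g1, g2) -> code`.
#' @return one-row tibble with `p_raw` and `degenerate`.
#' @export
interaction_test <- function(y, g1, g2, encoding = c("xor", "cartesian")) {
  enc <- encoding_funs(encoding)
  y <- phenotype_vector(y, length(g1))
  stopifnot(length(g1) == length(g2))
  X <- cbind(1, g1, g2, enc$pair(g1, g2))
  r <- ols_last_p(X, y)
  tibble::tibble(p_raw = r[1], degenerate = r[2] == 1)
}

#' Test a triple of loci for three-way epistasis
#'
#' Fits `y ~ 1 + g1 + g2 + g3 + code(g1,g2) + code(g1,g3) + code(g2,g3) +
#' code3(g1,g2,g3)` and returns the two-sided p-value for the three-way
#' coefficient, so the test asks for interaction signal beyond all pairwise
#' terms under the same encoding.
#'
#' @inheritParams interaction_test
#' @param g3 third genotype column.
#' @return one-row tibble with `p_raw` and `degenerate`.
#' @export
threeway_test <- function(y, g1, g2, g3, encoding = c("xor", "cartesian")) {
  enc <- encoding_funs(match.arg(encoding))
  y <- phenotype_vector(y, length(g1))
  stopifnot(length(g1) == length(g2), length(g2) == length(g3))
  X <- cbind(1, g1, g2, g3,
             enc$pair(g1, g2), enc$pair(g1, g3), enc$pair(g2, g3),
             enc$triple(g1, g2, g3))
  r <- ols_last_p(X, y)
  tibble::tibble(p_raw = r[1], degenerate = r[2] == 1)
}

#' Exhaustive pairwise epistasis scan
#'
#' Tests every unordered pair of post-filter loci with [interaction_test()]
#' under the chosen encoding, applies Benjamini-Hochberg FDR correction
#' across the full family of tested pairs, and flags pairs with adjusted
#' p-value below `alpha`. The adjusted p-value is the edge weight used by
#' [build_network()] and [sweep_threshold()].
#'
#' @param G a `geno_matrix`.
#' @param y phenotype vector or tibble.
#' @param encoding `"xor"` or `"cartesian"` (or a custom pair-code function).
#' @param min_maf minor-allele-frequency pruning threshold (inclusive).
#' @param alpha FDR level used for the `significant` flag.
#' @return an `epi_pairs` tibble: `snp_a`, `snp_b`, `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`, `p_raw`, `p_adj`, `significant`, `degenerate`,
#'   ordered by `(p_adj, chrom, pos)`. Within a pair, `snp_a` precedes
#'   `snp_b` in locus order. The encoding and alpha are carried as
#'   attributes.
#' @export
pairwise_scan <- function(G, y, encoding = c("xor", "cartesian"),
                          min_maf = 0.05, alpha = 0.05) {
  enc <- encoding_funs(encoding)
  stopifnot(inherits(G, "geno_matrix"))
  G <- maf_filter(G, min_maf)
  p <- ncol(G$codes)
  if (p < 2L) stop("fewer than 2 loci remain after MAF filtering", call. = FALSE)
  y <- phenotype_vector(y, nrow(G$codes))

  idx <- utils::combn(p, 2L)
  m <- ncol(idx)
  p_raw <- numeric(m)
  degen <- logical(m)
  for (t in seq_len(m)) {
    i <- idx[1L, t]; j <- idx[2L, t]
    g1 <- G$codes[, i]; g2 <- G$codes[, j]
    r <- ols_last_p(cbind(1, g1, g2, enc$pair(g1, g2)), y)
    p_raw[t] <- r[1]; degen[t] <- r[2] == 1
  }
  loci <- G$loci
  a <- idx[1L, ]; b <- idx[2L, ]
  # order endpoints within each pair by locus key
  swap <- locus_before(loci$chrom[b], loci$pos[b], loci$chrom[a], loci$pos[a])
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp

  out <- tibble::tibble(
    snp_a = loci$snp[a], snp_b = loci$snp[b],
    chrom_a = loci$chrom[a], pos_a = loci$pos[a],
    chrom_b = loci$chrom[b], pos_b = loci$pos[b],
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    degenerate = degen
  )
  out$significant <- out$p_adj < alpha
  out <- dplyr::arrange(out, .data$p_adj, .data$chrom_a, .data$pos_a,
                        .data$chrom_b, .data$pos_b)
  attr(out, "encoding") <- enc$name
  attr(out, "alpha") <- alpha
  class(out) <- c("epi_pairs", class(out))
  out
}

# strict locus ordering: is (c1, p1) before (c2, p2)?
locus_before <- function(c1, p1, c2, p2) {
  c1 <- normalize_chrom(c1); c2 <- normalize_chrom(c2)
  c1 < c2 | (c1 == c2 & p1 < p2)
}
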