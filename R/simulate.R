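#' Interaction encodings for two- and three-locus genotypes
#'
#' Genotypes are minor-allele counts in `{0, 1, 2}`. The Cartesian encoding is
#' the multiplicative product of the genotype codes. The XOR encoding is the
#' exclusive-or of the heterozygosity indicators, i.e. the penetrance table
#' with rows `0 1 0 / 1 0 1 / 0 1 0`: the phenotype depends only on the joint
#' genotype pattern, and at allele frequency 0.5 under Hardy-Weinberg
#' equilibrium the encoding has zero marginal single-locus effect, so it is
#' invisible to any single-locus analysis. Three-locus forms are the direct
#' generalizations: triple product and three-way parity of the heterozygosity
#' indicators.
#'
#' The two-locus XOR table is the package default; `interaction_code()`
#' dispatches on an `encoding` string so alternative penetrance tables can be
#' supplied as a function.
#'
#' @param g1,g2,g3 integer vectors of genotype codes in `{0, 1, 2}` (`NA`
#'   allowed; propagated).
#' @return integer vector of interaction codes: `{0, 1}` for XOR forms,
#'   `{0, ..., 4}` (`{0, ..., 8}` for triples) for Cartesian forms.
#' @export
#' @examples
#' encode_xor(c(0, 1, 2, 1), c(0, 1, 1, 2))
#' encode_cartesian(2, 2)
encode_xor <- function(g1, g2) {
  check_genotype(g1); check_genotype(g2)
  as.integer(xor(g1 == 1L, g2 == 1L))
}

#' @rdname encode_xor
#' @export
encode_cartesian <- function(g1, g2) {
  check_genotype(g1); check_genotype(g2)
  as.integer(g1) * as.integer(g2)
}

#' @rdname encode_xor
#' @export
encode_xor3 <- function(g1, g2, g3) {
  check_genotype(g1); check_genotype(g2); check_genotype(g3)
  as.integer(xor(xor(g1 == 1L, g2 == 1L), g3 == 1L))
}

#' @rdname encode_xor
#' @export
encode_cartesian3 <- function(g1, g2, g3) {
  check_genotype(g1); check_genotype(g2); check_genotype(g3)
  as.integer(g1) * as.integer(g2) * as.integer(g3)
}

check_genotype <- function(g) {
  ok <- is.na(g) | g %in% c(0L, 1L, 2L)
  if (!all(ok)) {
    stop("genotype codes must be 0, 1 or 2 (or NA); saw: ",
         paste(utils::head(unique(g[!ok]), 5L), collapse = ", "), call. = FALSE)
  }
  invisible(g)
}

# resolve an encoding spec to (pairwise, three-way) code functions
encoding_funs <- function(encoding) {
  if (is.function(encoding)) return(list(pair = encoding, triple = NULL, name = "custom"))
  encoding <- match.arg(encoding, c("xor", "cartesian"))
  if (encoding == "xor") {
    list(pair = encode_xor, triple = encode_xor3, name = "xor")
  } else {
    list(pair = encode_cartesian, triple = encode_cartesian3, name = "cartesian")
  }
}

#' Simulate genotype matrices under Hardy-Weinberg equilibrium
#'
#' Each locus is drawn i.i.d. with genotype probabilities
#' \eqn{((1-q)^2, 2q(1-q), q^2)} for minor-allele frequency \eqn{q}. Loci are
#' independent (no linkage disequilibrium is simulated).
#'
#' @param n_individuals number of individuals (rows).
#' @param loci tibble of loci as from [snp_loci()] (columns `snp`, `chrom`,
#'   `pos`).
#' @param maf minor-allele frequency in `(0, 0.5]`; scalar or one value per
#'   locus.
#' @param seed integer RNG seed; the same seed reproduces the matrix exactly.
#' @return a `geno_matrix`: list with `codes` (integer matrix, individuals x
#'   loci, columns named by SNP id) and `loci` (the coordinate tibble).
#' @export
#' @examples
#' G <- simulate_genotypes(100, snp_loci(5, seed = 1), maf = 0.3, seed = 42)
#' dim(G$codes)
simulate_genotypes <- function(n_individuals, loci, maf = 0.3, seed = NULL) {
  if (!is.numeric(n_individuals) || n_individuals < 1) {
    stop("n_individuals must be a positive count", call. = FALSE)
  }
  loci <- as_loci(loci)
  p <- nrow(loci)
  maf <- rep_len(maf, p)
  if (any(maf <= 0 | maf > 0.5)) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_individuals)
  codes <- vapply(maf, function(q) {
    sample(0:2, n, replace = TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }, integer(n))
  codes <- matrix(codes, nrow = n, ncol = p,
                  dimnames = list(NULL, loci$snp))
  new_geno_matrix(codes, loci)
}

new_geno_matrix <- function(codes, loci) {
  stopifnot(ncol(codes) == nrow(loci))
  structure(list(codes = codes, loci = loci), class = "geno_matrix")
}

as_loci <- function(loci) {
  if (is.character(loci)) loci <- parse_snp_id(loci)
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("chrom", "pos") %in% names(loci)))
  loci$chrom <- normalize_chrom(loci$chrom)
  if (is.null(loci$snp)) loci$snp <- format_snp_id(loci$chrom, loci$pos)
  if (anyDuplicated(loci[c("chrom", "pos")])) {
    stop("duplicate (chromosome, position) keys in loci", call. = FALSE)
  }
  loci[c("snp", "chrom", "pos")]
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$codes), " individuals x ", ncol(x$codes),
      " SNPs\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Specify a planted epistatic architecture
#'
#' Describes which locus pairs/triples carry Cartesian or XOR interaction
#' effects of given size, plus the residual noise level, for
#' [simulate_phenotype()].
#'
#' @param pairs tibble (or data frame) with columns `a`, `b` (locus column
#'   indices or SNP ids), `model` (`"xor"` or `"cartesian"`) and `beta`
#'   (effect size per unit interaction code). May be `NULL`.
#' @param triples as `pairs` with columns `a`, `b`, `c`.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (must be > 0; the trait is quantitative).
#' @return an `epi_architecture` object.
#' @export
#' @examples
#' arch <- epi_architecture(pairs = data.frame(a = 1, b = 2,
#'                                             model = "xor", beta = 1))
epi_architecture <- function(pairs = NULL, triples = NULL, noise_sd = 1) {
  if (!is.numeric(noise_sd) || noise_sd <= 0 || !is.finite(noise_sd)) {
    stop("noise_sd must be a positive finite number", call. = FALSE)
  }
  check_terms <- function(df, cols) {
    if (is.null(df)) return(NULL)
    df <- tibble::as_tibble(df)
    stopifnot(all(c(cols, "model", "beta") %in% names(df)))
    if (!all(df$model %in% c("xor", "cartesian"))) {
      stop("model must be 'xor' or 'cartesian'", call. = FALSE)
    }
    if (!all(is.finite(df$beta))) stop("beta must be finite", call. = FALSE)
    idx <- df[cols]
    if (any(apply(idx, 1L, anyDuplicated) > 0)) {
      stop("planted loci must be distinct within a term", call. = FALSE)
    }
    df
  }
  structure(list(pairs = check_terms(pairs, c("a", "b")),
                 triples = check_terms(triples, c("a", "b", "c")),
                 noise_sd = noise_sd),
            class = "epi_architecture")
}

resolve_index <- function(i, G) {
  if (is.character(i)) {
    j <- match(i, colnames(G$codes))
    if (anyNA(j)) stop("unknown SNP id: ", paste(i[is.na(j)], collapse = ", "),
                       call. = FALSE)
    return(j)
  }
  j <- as.integer(i)
  if (any(j < 1L | j > ncol(G$codes))) {
    stop("locus index out of range", call. = FALSE)
  }
  j
}

#' Simulate a quantitative phenotype from a planted architecture
#'
#' The phenotype is the sum of the planted interaction terms plus additive
#' Gaussian noise:
#' \eqn{y = \sum \beta \, code(g_i, g_j) + \sum \beta \, code_3(g_i, g_j, g_k) + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)}. No main effects are planted; under a
#' pure XOR architecture at MAF 0.5 the trait has no marginal single-locus
#' signal.
#'
#' @param G a `geno_matrix` from [simulate_genotypes()].
#' @param arch an [epi_architecture()] (default: pure noise).
#' @param seed integer RNG seed.
#' @param trait_name label attached to the result.
#' @return tibble with columns `individual` and `phenotype`.
#' @export
simulate_phenotype <- function(G, arch = epi_architecture(), seed = NULL,
                               trait_name = "SYNTH_TRAIT") {
  stopifnot(inherits(G, "geno_matrix"), inherits(arch, "epi_architecture"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G$codes)
  y <- numeric(n)
  if (!is.null(arch$pairs)) {
    for (r in seq_len(nrow(arch$pairs))) {
      i <- resolve_index(arch$pairs$a[r], G)
      j <- resolve_index(arch$pairs$b[r], G)
      code <- encoding_funs(arch$pairs$model[r])$pair
      y <- y + arch$pairs$beta[r] * code(G$codes[, i], G$codes[, j])
    }
  }
  if (!is.null(arch$triples)) {
    for (r in seq_len(nrow(arch$triples))) {
      i <- resolve_index(arch$triples$a[r], G)
      j <- resolve_index(arch$triples$b[r], G)
      k <- resolve_index(arch$triples$c[r], G)
      code3 <- encoding_funs(arch$triples$model[r])$triple
      y <- y + arch$triples$beta[r] * code3(G$codes[, i], G$codes[, j], G$codes[, k])
    }
  }
  y <- y + stats::rnorm(n, 0, arch$noise_sd)
  out <- tibble::tibble(individual = paste0("ind", seq_len(n)), phenotype = y)
  attr(out, "trait_name") <- trait_name
  out
}

# coerce a phenotype argument (tibble or numeric) to a plain vector
phenotype_vector <- function(y, n = NULL) {
  if (is.data.frame(y)) {
    stopifnot("phenotype" %in% names(y))
    y <- y$phenotype
  }
  y <- as.numeric(y)
  if (!is.null(n) && length(y) != n) {
    stop("phenotype length (", length(y), ") does not match the number of ",
         "individuals (", n, ")", call. = FALSE)
  }
  if (!all(is.finite(y))) stop("phenotype values must be finite", call. = FALSE)
  y
}
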