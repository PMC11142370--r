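#' Enumerate triangle motifs in an epistatic network
#'
#' A triangle is an unordered node triple with all three pairwise edges
#' present — three SNPs all mutually epistatic at the network's threshold.
#' Triangles nominate candidate three-way interactions because a genuine
#' higher-order effect tends to leave pairwise traces on all three pairs,
#' while a clique of positionally adjacent SNPs is more likely linkage
#' disequilibrium. Each triangle is listed once with its loci in locus order.
#'
#' @param net an `epi_network`.
#' @return an `epi_triangles` tibble: `snp_1..snp_3`, `chrom_1..chrom_3`,
#'   `pos_1..pos_3`, `w_12`, `w_13`, `w_23` (edge weights), `chrom_pattern`
#'   (`"all_same_chromosome"`, `"two_shared"`, `"all_different"`) and `span`
#'   (largest pairwise distance in bp when all loci share a chromosome,
#'   else `NA`). Rows ordered by locus keys.
#' @export
enumerate_triangles <- function(net) {
  stopifnot(inherits(net, "epi_network"))
  empty <- tibble::tibble(
    snp_1 = character(), snp_2 = character(), snp_3 = character(),
    chrom_1 = character(), chrom_2 = character(), chrom_3 = character(),
    pos_1 = numeric(), pos_2 = numeric(), pos_3 = numeric(),
    w_12 = numeric(), w_13 = numeric(), w_23 = numeric(),
    chrom_pattern = character(), span = numeric()
  )
  if (nrow(net$edges) == 0L) return(structure(empty, class = c("epi_triangles", class(empty))))
  g <- as_igraph(net)
  tri <- igraph::triangles(g)
  if (length(tri) == 0L) return(structure(empty, class = c("epi_triangles", class(empty))))
  ids <- igraph::V(g)$name
  tri <- matrix(ids[as.integer(tri)], ncol = 3L, byrow = TRUE)
  nodes <- net$nodes
  wkey <- stats::setNames(net$edges$weight,
                          paste(net$edges$snp_a, net$edges$snp_b))
  rows <- purrr::map_dfr(seq_len(nrow(tri)), function(t) {
    trio <- nodes[match(tri[t, ], nodes$snp), ]
    trio <- trio[locus_order(trio$chrom, trio$pos), ]
    ew <- function(i, j) {
      k <- paste(trio$snp[i], trio$snp[j])
      if (is.na(wkey[k])) wkey[paste(trio$snp[j], trio$snp[i])] else wkey[k]
    }
    tibble::tibble(
      snp_1 = trio$snp[1L], snp_2 = trio$snp[2L], snp_3 = trio$snp[3L],
      chrom_1 = trio$chrom[1L], chrom_2 = trio$chrom[2L], chrom_3 = trio$chrom[3L],
      pos_1 = trio$pos[1L], pos_2 = trio$pos[2L], pos_3 = trio$pos[3L],
      w_12 = unname(ew(1L, 2L)), w_13 = unname(ew(1L, 3L)),
      w_23 = unname(ew(2L, 3L))
    )
  })
  rows <- dplyr::arrange(rows, .data$chrom_1, .data$pos_1, .data$chrom_2,
                         .data$pos_2, .data$chrom_3, .data$pos_3)
  n_chrom <- apply(rows[c("chrom_1", "chrom_2", "chrom_3")], 1L,
                   function(z) length(unique(z)))
  rows$chrom_pattern <- c("all_same_chromosome", "two_shared",
                          "all_different")[n_chrom]
  rows$span <- ifelse(
    n_chrom == 1L,
    pmax(rows$pos_2 - rows$pos_1, rows$pos_3 - rows$pos_2,
         rows$pos_3 - rows$pos_1),
    NA_real_
  )
  structure(rows, class = c("epi_triangles", class(rows)))
}

#' Classify triangles by chromosomal dispersion
#'
#' Adds a `cis_flag`: `TRUE` when all three loci share a chromosome and the
#' triangle's span is at most `proximity_bp`. Tight same-chromosome
#' triangles are candidate linkage-disequilibrium artefacts (or cis-acting
#' clusters) rather than genuine trans higher-order epistasis.
#'
#' @param tris an `epi_triangles` tibble from [enumerate_triangles()].
#' @param proximity_bp span cutoff in base pairs (default 2 Mb).
#' @return the input with a `cis_flag` logical column.
#' @export
classify_triangles <- function(tris, proximity_bp = 2e6) {
  stopifnot(proximity_bp >= 0)
  tris$cis_flag <- !is.na(tris$span) & tris$span <= proximity_bp
  tris
}

#' Test triangles for three-way epistasis
#'
#' Runs [threeway_test()] for every triangle (full model: main effects, all
#' pairwise codes and the three-way code), adjusts across the triangle set
#' with Benjamini-Hochberg, and flags triangles with adjusted p below
#' `alpha`. Triangles whose loci cannot be resolved to genotype columns are
#' skipped with a warning and carry `NA` p-values.
#'
#' @param tris an `epi_triangles` tibble.
#' @param G a `geno_matrix` holding the triangle loci as columns.
#' @param y phenotype vector or tibble.
#' @param encoding `"xor"` or `"cartesian"`.
#' @param alpha FDR level for the `significant` flag.
#' @return the input annotated with `p3_raw`, `p3_adj`, `degenerate` and
#'   `significant`, ordered by `p3_adj` then locus keys.
#' @export
test_triangles <- function(tris, G, y, encoding = c("xor", "cartesian"),
                           alpha = 0.05) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(G, "geno_matrix"))
  y <- phenotype_vector(y, nrow(G$codes))
  n_tri <- nrow(tris)
  p3 <- rep(NA_real_, n_tri)
  degen <- rep(NA, n_tri)
  if (n_tri > 0L) {
    cols <- colnames(G$codes)
    for (t in seq_len(n_tri)) {
      idx <- match(c(tris$snp_1[t], tris$snp_2[t], tris$snp_3[t]), cols)
      if (anyNA(idx)) {
        warning("triangle ", t, ": locus not found in genotype matrix; skipped",
                call. = FALSE)
        next
      }
      r <- threeway_test(y, G$codes[, idx[1L]], G$codes[, idx[2L]],
                         G$codes[, idx[3L]], encoding)
      p3[t] <- r$p_raw
      degen[t] <- r$degenerate
    }
  }
  tris$p3_raw <- p3
  tris$p3_adj <- NA_real_
  tested <- !is.na(p3)
  if (any(tested)) tris$p3_adj[tested] <- bh_adjust(p3[tested])
  tris$degenerate <- degen
  tris$significant <- !is.na(tris$p3_adj) & tris$p3_adj < alpha
  attr(tris, "encoding") <- encoding
  attr(tris, "alpha") <- alpha
  dplyr::arrange(tris, .data$p3_adj, .data$chrom_1, .data$pos_1,
                 .data$chrom_2, .data$pos_2, .data$chrom_3, .data$pos_3)
}

#' Multigraph of significant triangles
#'
#' Collects the pairwise edges of the significant triangles, one parallel
#' edge per containing triangle, so a SNP pair shared by several significant
#' triangles appears with that multiplicity.
#'
#' @param tris a tested `epi_triangles` tibble (from [test_triangles()]).
#' @return tibble with `snp_a`, `snp_b`, `weight` and `triangle_id` (row
#'   index of the contributing triangle); convertible to an igraph
#'   multigraph with [igraph::graph_from_data_frame()].
#' @export
triangle_multigraph <- function(tris) {
  if (is.null(tris$significant)) {
    stop("run test_triangles() first", call. = FALSE)
  }
  sig <- which(tris$significant)
  purrr::map_dfr(sig, function(t) {
    tibble::tibble(
      snp_a = c(tris$snp_1[t], tris$snp_1[t], tris$snp_2[t]),
      snp_b = c(tris$snp_2[t], tris$snp_3[t], tris$snp_3[t]),
      weight = c(tris$w_12[t], tris$w_13[t], tris$w_23[t]),
      triangle_id = t
    )
  })
}
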