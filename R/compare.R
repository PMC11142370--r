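#' Positional-tolerance identity of SNPs and edges
#'
#' Nearby SNPs are treated as interchangeable because linkage disequilibrium
#' makes their signals redundant. Two loci match within tolerance `delta`
#' when they lie on the same chromosome and their positions differ by at most
#' `delta` base pairs (inclusive, so `delta = 0` is exact identity). Two
#' edges match when their endpoints match pairwise in either orientation.
#'
#' @param a,b SNP identifiers (character, any supported dialect) or tibbles
#'   with `chrom`/`pos` columns; recycled elementwise.
#' @param e_a,e_b edges: length-2 character vectors of SNP ids (or 2-row
#'   loci tibbles).
#' @param delta tolerance in base pairs (>= 0).
#' @return logical.
#' @export
#' @examples
#' nodes_match("chr1.100", "1:150", delta = 50)
#' edges_match(c("chr1.100", "chr2.200"), c("2:200", "1:100"), delta = 0)
nodes_match <- function(a, b, delta) {
  stopifnot(delta >= 0)
  a <- as_loci_any(a)
  b <- as_loci_any(b)
  a$chrom == b$chrom & abs(a$pos - b$pos) <= delta
}

#' @rdname nodes_match
#' @export
edges_match <- function(e_a, e_b, delta) {
  a <- as_loci_any(e_a)
  b <- as_loci_any(e_b)
  stopifnot(nrow(a) == 2L, nrow(b) == 2L)
  m <- function(i, j) a$chrom[i] == b$chrom[j] & abs(a$pos[i] - b$pos[j]) <= delta
  stopifnot(delta >= 0)
  (m(1L, 1L) && m(2L, 2L)) || (m(1L, 2L) && m(2L, 1L))
}

as_loci_any <- function(x) {
  if (is.character(x)) return(parse_snp_id(x))
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "pos") %in% names(x)))
  x$chrom <- normalize_chrom(x$chrom)
  x
}

# logical matrix: rows = a loci, cols = b loci, TRUE where within tolerance
node_match_matrix <- function(a, b, delta) {
  outer(a$chrom, b$chrom, `==`) & abs(outer(a$pos, b$pos, `-`)) <= delta
}

#' Node and edge overlap between two networks over a tolerance grid
#'
#' For each tolerance `delta` and each direction, counts the elements of the
#' first network (nodes, then edges) having at least one tolerant match in
#' the second, and expresses them as percentages of the first network's own
#' totals. Matching is existential: an element counts once however many
#' counterparts it has.
#'
#' @param net_a,net_b `epi_network` objects (both non-empty).
#' @param delta_grid tolerances in base pairs (default 0 to 10 Mb by 1 Mb).
#' @return tibble with columns `direction` (`"a_to_b"`/`"b_to_a"`), `type`
#'   (`"node"`/`"edge"`), `delta`, `matched`, `total`, `percentage`.
#' @export
match_report <- function(net_a, net_b, delta_grid = seq(0, 1e7, by = 1e6)) {
  stopifnot(inherits(net_a, "epi_network"), inherits(net_b, "epi_network"))
  if (nrow(net_a$edges) == 0L || nrow(net_b$edges) == 0L) {
    stop("both networks must be non-empty", call. = FALSE)
  }
  one_dir <- function(na, nb, label) {
    ea <- edge_indices(na)
    eb <- edge_indices(nb)
    purrr::map_dfr(delta_grid, function(d) {
      mm <- node_match_matrix(na$nodes, nb$nodes, d)
      node_hit <- rowSums(mm) > 0
      # a-edge (u1,u2) matches b-edge (v1,v2) in either orientation
      bv1 <- eb[, 1L]; bv2 <- eb[, 2L]
      edge_hit <- vapply(seq_len(nrow(ea)), function(t) {
        m1 <- mm[ea[t, 1L], ]; m2 <- mm[ea[t, 2L], ]
        any((m1[bv1] & m2[bv2]) | (m1[bv2] & m2[bv1]))
      }, logical(1L))
      tibble::tibble(
        direction = label,
        type = c("node", "edge"),
        delta = d,
        matched = c(sum(node_hit), sum(edge_hit)),
        total = c(nrow(na$nodes), nrow(ea)),
        percentage = 100 * .data$matched / .data$total
      )
    })
  }
  dplyr::bind_rows(one_dir(net_a, net_b, "a_to_b"),
                   one_dir(net_b, net_a, "b_to_a")) |>
    dplyr::arrange(.data$direction, dplyr::desc(.data$type), .data$delta)
}

#' Directional community similarity count
#'
#' \eqn{\Lambda_{(C_a \to C_b)}(\delta)}: the number of nodes of community
#' `C_a` having at least one tolerant positional match among the nodes of
#' community `C_b`. Directional — normalization and totals always refer to
#' `C_a`.
#'
#' @param c_a,c_b community node sets: character SNP ids or tibbles with
#'   `chrom`/`pos`. `c_a` must be non-empty.
#' @param delta tolerance in base pairs.
#' @return integer count in `[0, |C_a|]`.
#' @export
community_lambda <- function(c_a, c_b, delta) {
  a <- as_loci_any(c_a)
  if (nrow(a) == 0L) stop("community C_a is empty", call. = FALSE)
  b <- as_loci_any(c_b)
  if (nrow(b) == 0L) return(0L)
  sum(rowSums(node_match_matrix(a, b, delta)) > 0)
}

#' Community similarity curve and its (normalized) area under the curve
#'
#' Evaluates \eqn{\Lambda_{(C_a \to C_b)}(\delta)} on the grid
#' \eqn{\delta_{min}, \delta_{min}+s, \ldots, \delta_{max}} and summarizes it
#' as \deqn{AUC = \sum_{k=0}^{M} \frac{\Lambda(\delta_{min}+ks) +
#' \Lambda(\delta_{min}+(k+1)s)}{2(M+1)}, \quad M =
#' \frac{\delta_{max}-\delta_{min}}{s} - 1,} normalized by the size of the
#' source community: \eqn{AUC_{norm} = AUC / |C_a| \in [0, 1]}, reaching 1
#' exactly when \eqn{\Lambda} saturates at every grid point. The default
#' grid spans 0 to 10 Mb in 1 Mb steps.
#'
#' @inheritParams community_lambda
#' @param delta_min,delta_max,s grid bounds and step in base pairs
#'   (`s > 0`, `delta_max > delta_min`, span divisible by `s`).
#' @return one-row tibble with `auc`, `auc_norm`, `size_a` and a
#'   `lambda_curve` list-column (tibble of `delta`, `lambda`).
#' @export
community_auc <- function(c_a, c_b, delta_min = 0, delta_max = 1e7, s = 1e6) {
  stopifnot(s > 0, delta_max > delta_min)
  a <- as_loci_any(c_a)
  if (nrow(a) == 0L) stop("community C_a is empty", call. = FALSE)
  deltas <- seq(delta_min, delta_max, by = s)
  lambda <- vapply(deltas, function(d) as.numeric(community_lambda(a, c_b, d)),
                   numeric(1L))
  m_steps <- (delta_max - delta_min) / s - 1
  auc <- sum(lambda[-length(lambda)] + lambda[-1L]) / (2 * (m_steps + 1))
  tibble::tibble(
    auc = auc,
    auc_norm = auc / nrow(a),
    size_a = nrow(a),
    lambda_curve = list(tibble::tibble(delta = deltas, lambda = lambda))
  )
}

#' Directional community-similarity matrices between two partitions
#'
#' Every community of one partition is compared against every community of
#' the other in both directions; entry (i, j) of the `a_to_b` matrix is the
#' normalized AUC of \eqn{\Lambda_{(C_i^a \to C_j^b)}}. Because the score is
#' normalized by the source community's size, the two matrices are not
#' transposes of one another.
#'
#' @param partition_a,partition_b `epi_partition` objects from
#'   [detect_communities()].
#' @inheritParams community_auc
#' @return an `epi_similarity`: list with `a_to_b` and `b_to_a` matrices
#'   (rows = source communities, ordered by descending size) and `scores`, a
#'   long tibble (`direction`, `community_a`, `community_b`, `size_a`,
#'   `auc`, `auc_norm`).
#' @export
similarity_matrices <- function(partition_a, partition_b,
                                delta_min = 0, delta_max = 1e7, s = 1e6) {
  stopifnot(inherits(partition_a, "epi_partition"),
            inherits(partition_b, "epi_partition"))
  split_comm <- function(p) split(p$membership, p$membership$community)
  ca <- split_comm(partition_a)
  cb <- split_comm(partition_b)
  one_dir <- function(from, to, label) {
    purrr::map_dfr(names(from), function(i) {
      purrr::map_dfr(names(to), function(j) {
        r <- community_auc(from[[i]], to[[j]], delta_min, delta_max, s)
        tibble::tibble(direction = label,
                       community_a = as.integer(i),
                       community_b = as.integer(j),
                       size_a = r$size_a, auc = r$auc, auc_norm = r$auc_norm)
      })
    })
  }
  scores <- dplyr::bind_rows(one_dir(ca, cb, "a_to_b"),
                             one_dir(cb, ca, "b_to_a"))
  to_matrix <- function(df) {
    wide <- tidyr::pivot_wider(df[c("community_a", "community_b", "auc_norm")],
                               names_from = "community_b",
                               values_from = "auc_norm")
    m <- as.matrix(wide[-1L])
    rownames(m) <- wide$community_a
    m
  }
  structure(list(
    a_to_b = to_matrix(scores[scores$direction == "a_to_b", ]),
    b_to_a = to_matrix(scores[scores$direction == "b_to_a", ]),
    scores = scores
  ), class = "epi_similarity")
}

#' @export
print.epi_similarity <- function(x, ...) {
  cat("<epi_similarity> a->b: ", nrow(x$a_to_b), "x", ncol(x$a_to_b),
      ", b->a: ", nrow(x$b_to_a), "x", ncol(x$b_to_a),
      " (normalized AUC)\n", sep = "")
  invisible(x)
}
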