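#' Pair-table dialect description
#'
#' Deposited interaction tables differ in column naming and SNP id syntax;
#' a dialect maps them onto the package's canonical pair table. Both SNP id
#' syntaxes (`chr{c}.{pos}` and `{c}:{pos}`) are always accepted.
#'
#' @param snp_a,snp_b,p_adj column names in the file.
#' @param delim field delimiter (default tab).
#' @return a `pair_dialect` list.
#' @export
pair_dialect <- function(snp_a = "snp_a", snp_b = "snp_b", p_adj = "p_adj",
                         delim = "\t") {
  structure(list(snp_a = snp_a, snp_b = snp_b, p_adj = p_adj, delim = delim),
            class = "pair_dialect")
}

#' Read and write pair tables
#'
#' Reads a delimited table of tested SNP pairs with FDR-adjusted p-values
#' (edge weights). Duplicate unordered pairs are collapsed to their smallest
#' weight with a warning; p-values outside `[0, 1]` and malformed ids raise
#' parse errors naming the offending data line.
#'
#' @param path file path.
#' @param dialect a [pair_dialect()].
#' @return tibble with `snp_a`, `snp_b`, `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`, `p_adj`, endpoint-ordered and locus-sorted.
#' @export
read_pairs <- function(path, dialect = pair_dialect()) {
  raw <- readr::read_delim(path, delim = dialect$delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  need <- c(dialect$snp_a, dialect$snp_b, dialect$p_adj)
  if (!all(need %in% names(raw))) {
    stop("pair table is missing column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  p <- suppressWarnings(as.numeric(raw[[dialect$p_adj]]))
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad)) {
    stop("invalid p-value at data line ", bad[1L], ": ",
         raw[[dialect$p_adj]][bad[1L]], call. = FALSE)
  }
  for (col in c(dialect$snp_a, dialect$snp_b)) {
    ok <- tryCatch({parse_snp_id(raw[[col]]); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) stop("in column '", col, "': ", ok, call. = FALSE)
  }
  ed <- canonical_edges(
    tibble::tibble(snp_a = raw[[dialect$snp_a]], snp_b = raw[[dialect$snp_b]],
                   p_adj = p),
    warn_dupes = TRUE)
  dplyr::rename(ed, p_adj = "weight")
}

#' @rdname read_pairs
#' @param pairs a pair tibble (as from [pairwise_scan()] or [read_pairs()]).
#' @export
write_pairs <- function(pairs, path) {
  keep <- intersect(c("snp_a", "snp_b", "p_raw", "p_adj", "significant"),
                    names(pairs))
  readr::write_tsv(pairs[keep], path, progress = FALSE)
  invisible(path)
}

#' Read and write genotype matrices and phenotypes
#'
#' The canonical genotype format is a TSV matrix: first column `individual`,
#' remaining columns one SNP each (header = SNP id in either dialect), cells
#' in `{0, 1, 2}` or `NA` for missing. Phenotypes are a two-column TSV
#' (`individual`, `phenotype`); on read the individuals must align with the
#' genotype file.
#'
#' @param path file path.
#' @return [read_genotypes()]: a `geno_matrix`; [read_phenotype()]: a tibble
#'   `individual`, `phenotype`.
#' @export
read_genotypes <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(raw)[1L] != "individual") {
    stop("first column must be 'individual'", call. = FALSE)
  }
  codes <- as.matrix(raw[-1L])
  mode(codes) <- "integer"
  bad <- !is.na(codes) & !(codes %in% c(0L, 1L, 2L))
  if (any(bad)) {
    stop("invalid genotype code(s): ",
         paste(utils::head(unique(codes[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  loci <- parse_snp_id(colnames(raw)[-1L])
  colnames(codes) <- loci$snp
  G <- new_geno_matrix(codes, loci)
  attr(G, "individuals") <- raw$individual
  G
}

#' @rdname read_genotypes
#' @param G a `geno_matrix`.
#' @param individuals optional individual ids (default `ind1..indN`).
#' @export
write_genotypes <- function(G, path, individuals = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is.null(individuals)) {
    individuals <- attr(G, "individuals") %||%
      paste0("ind", seq_len(nrow(G$codes)))
  }
  out <- tibble::as_tibble(G$codes)
  out <- dplyr::bind_cols(tibble::tibble(individual = individuals), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_genotypes
#' @export
read_phenotype <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("individual", "phenotype") %in% names(raw))) {
    stop("phenotype file needs 'individual' and 'phenotype' columns",
         call. = FALSE)
  }
  if (!is.numeric(raw$phenotype) || any(!is.finite(raw$phenotype))) {
    stop("phenotype values must be finite numbers", call. = FALSE)
  }
  raw[c("individual", "phenotype")]
}

#' @rdname read_genotypes
#' @param y phenotype tibble (`individual`, `phenotype`).
#' @export
write_phenotype <- function(y, path) {
  readr::write_tsv(y[c("individual", "phenotype")], path, progress = FALSE)
  invisible(path)
}

#' Align a phenotype to a genotype matrix by individual id
#'
#' @param G a `geno_matrix` read with [read_genotypes()].
#' @param y a phenotype tibble.
#' @return numeric phenotype vector in genotype row order.
#' @export
align_phenotype <- function(G, y) {
  ind <- attr(G, "individuals")
  if (is.null(ind)) {
    return(phenotype_vector(y, nrow(G$codes)))
  }
  idx <- match(ind, y$individual)
  if (anyNA(idx)) {
    stop("phenotype is missing individual(s): ",
         paste(utils::head(ind[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  y$phenotype[idx]
}

#' Export networks, sweeps and similarity results
#'
#' Networks are written as an edge-list TSV (`snp_a`, `snp_b`, `weight`,
#' locus-sorted, byte-identical across runs) or as GraphML with `chrom` and
#' `pos` vertex attributes and edge `weight`. Sweeps are written one grid
#' row per threshold; similarity results as the long score table.
#'
#' @param net an `epi_network`.
#' @param path output file path.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @return the path, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(net, "epi_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(net$edges, path, progress = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @param path_or_pairs for `read_network`: an edge-list TSV written by
#'   [export_network()].
#' @param tau threshold recorded on the re-read network (default `Inf`
#'   keeps every stored edge).
#' @export
read_network <- function(path_or_pairs, tau = Inf) {
  ed <- readr::read_tsv(path_or_pairs, show_col_types = FALSE, progress = FALSE)
  build_network(ed, tau = if (is.finite(tau)) tau else max(ed$weight))
}

#' @rdname export_network
#' @param sweep an `epi_sweep`.
#' @export
export_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "epi_sweep"))
  readr::write_tsv(sweep$grid, path, progress = FALSE)
  invisible(path)
}

#' @rdname export_network
#' @param sim an `epi_similarity`.
#' @export
export_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "epi_similarity"))
  readr::write_tsv(sim$scores, path, progress = FALSE)
  invisible(path)
}

#' Prepare g:Profiler range queries around SNPs
#'
#' Functional enrichment of SNP lists uses genomic ranges: every SNP is
#' expanded by `flank` base pairs up- and downstream (default 1 Mb), the
#' start clamped at 1, and formatted as `"{c}:{start}:{end}"` — e.g. SNP
#' `1:12345678` with a 1 Mb flank becomes `"1:11345678:13345678"`.
#' Degenerate ranges (end not beyond start, as with `flank = 0`) are dropped
#' with a warning.
#'
#' @param snps SNP ids (character) or a loci tibble (`chrom`, `pos`).
#' @param flank flank size in base pairs (>= 0).
#' @param path optional: write the ranges one per line to this file.
#' @return tibble with `chrom`, `start`, `end`, `range`
#'   (the formatted query string).
#' @export
export_gprofiler_ranges <- function(snps, flank = 1e6, path = NULL) {
  stopifnot(flank >= 0)
  loci <- as_loci_any(snps)
  out <- tibble::tibble(
    chrom = loci$chrom,
    start = pmax(1, loci$pos - flank),
    end = loci$pos + flank
  )
  bad <- out$end <= out$start
  if (any(bad)) {
    warning(sum(bad), " degenerate range(s) dropped (end must exceed start)",
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out$range <- paste0(out$chrom, ":",
                      format(out$start, scientific = FALSE, trim = TRUE), ":",
                      format(out$end, scientific = FALSE, trim = TRUE))
  if (!is.null(path)) writeLines(out$range, path)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
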