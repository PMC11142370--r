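#' Normalize chromosome labels
#'
#' Chromosome labels arrive in mixed notations (`"chr1"`, `"1"`, `"Chr X"`).
#' All positional comparisons in the package first normalize labels by
#' lower-casing and stripping a leading `"chr"` prefix, so `"chr1"` and `"1"`
#' refer to the same chromosome.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "1", "ChrX"))
normalize_chrom <- function(chrom) {
  out <- tolower(trimws(as.character(chrom)))
  sub("^chr", "", out)
}

#' Parse SNP identifiers into chromosome and position
#'
#' Two identifier dialects are understood and produce identical loci:
#' `"chr{c}.{pos}"` (e.g. `"chr1.281788173"`) and `"{c}:{pos}"`
#' (e.g. `"1:281788173"`). Positions are 1-based base pairs.
#'
#' @param id character vector of SNP identifiers.
#' @return a tibble with columns `snp` (the normalized `chr{c}.{pos}` form),
#'   `chrom` (normalized label) and `pos` (numeric base pairs).
#' @export
#' @examples
#' parse_snp_id(c("chr1.281788173", "1:281788173"))
parse_snp_id <- function(id) {
  id <- as.character(id)
  colon <- grepl(":", id, fixed = TRUE)
  dotted <- grepl("^chr", id, ignore.case = TRUE) & grepl(".", id, fixed = TRUE)
  bad <- !colon & !dotted
  if (any(bad)) {
    stop("malformed SNP id(s): ", paste(utils::head(id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  chrom <- character(length(id))
  pos_chr <- character(length(id))
  if (any(colon)) {
    parts <- strsplit(id[colon], ":", fixed = TRUE)
    chrom[colon] <- vapply(parts, `[`, "", 1L)
    pos_chr[colon] <- vapply(parts, `[`, "", 2L)
  }
  if (any(!colon)) {
    body <- sub("^chr", "", id[!colon], ignore.case = TRUE)
    dot <- regexpr(".", body, fixed = TRUE)
    chrom[!colon] <- substr(body, 1L, dot - 1L)
    pos_chr[!colon] <- substr(body, dot + 1L, nchar(body))
  }
  pos <- suppressWarnings(as.numeric(pos_chr))
  if (anyNA(pos) || any(pos < 1) || any(pos != floor(pos))) {
    stop("malformed SNP position in id(s): ",
         paste(utils::head(id[is.na(pos) | pos < 1], 5L), collapse = ", "),
         call. = FALSE)
  }
  chrom <- normalize_chrom(chrom)
  tibble::tibble(snp = format_snp_id(chrom, pos), chrom = chrom, pos = pos)
}

#' Format loci as canonical SNP identifiers
#'
#' @param chrom chromosome labels (normalized internally).
#' @param pos positions in base pairs.
#' @param style `"dot"` for `chr{c}.{pos}` (default) or `"colon"` for
#'   `{c}:{pos}`.
#' @return character vector of identifiers.
#' @export
format_snp_id <- function(chrom, pos, style = c("dot", "colon")) {
  style <- match.arg(style)
  chrom <- normalize_chrom(chrom)
  pos <- format(pos, scientific = FALSE, trim = TRUE)
  if (style == "dot") paste0("chr", chrom, ".", pos) else paste0(chrom, ":", pos)
}

#' Construct a table of SNP loci
#'
#' Convenience generator for simulation studies: places `n_snps` loci across
#' `n_chrom` chromosomes at positions drawn without replacement from
#' `1..max_pos`.
#'
#' @param n_snps number of loci.
#' @param n_chrom number of chromosomes to spread them over.
#' @param max_pos largest base-pair position (default 100 Mb, the scale of a
#'   mammalian chromosome).
#' @param seed optional integer seed for reproducible placement.
#' @return tibble with columns `snp`, `chrom`, `pos`, sorted by locus key.
#' @export
snp_loci <- function(n_snps, n_chrom = 5L, max_pos = 1e8, seed = NULL) {
  stopifnot(n_snps >= 1L, n_chrom >= 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  chrom <- as.character(rep_len(seq_len(n_chrom), n_snps))
  pos <- floor(stats::runif(n_snps, 1, max_pos))
  # resolve collisions on the same chromosome
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    pos[dup] <- floor(stats::runif(sum(dup), 1, max_pos))
    key <- paste(chrom, pos)
  }
  out <- tibble::tibble(snp = format_snp_id(chrom, pos), chrom = chrom, pos = pos)
  dplyr::arrange(out, .data$chrom, .data$pos)
}

# deterministic ordering key used everywhere results are sorted
locus_order <- function(chrom, pos) order(normalize_chrom(chrom), pos)
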