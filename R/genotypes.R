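# Core genotype container: animals x SNP allele-dosage matrix plus map.

#' Construct a genotype matrix
#'
#' Animals-by-SNP matrix of allele dosages coded 0 (one homozygote),
#' 1 (heterozygote), 2 (other homozygote), with a physical map giving each
#' SNP's chromosome and 1-based bp position. This is the incidence matrix X
#' of the marker-effects model.
#'
#' @param codes integer matrix, rows = animals, columns = SNP; entries in
#'   `{0, 1, 2}` (`NA` allowed only when explicitly permitted downstream).
#' @param animal_ids character vector of row labels.
#' @param snp_ids character vector of column labels; must be unique.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   one row per SNP, sorted by position within chromosome.
#' @param allow_missing logical; permit `NA` codes (pre-imputation only).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(codes, animal_ids, snp_ids, map,
                            allow_missing = FALSE) {
  codes <- as.matrix(codes)
  if (length(animal_ids) != nrow(codes))
    stop_ld("animal_ids length (%d) != rows of codes (%d)",
            length(animal_ids), nrow(codes))
  if (length(snp_ids) != ncol(codes))
    stop_ld("snp_ids length (%d) != columns of codes (%d)",
            length(snp_ids), ncol(codes))
  if (anyDuplicated(snp_ids))
    stop_ld("duplicate snp_id: %s",
            paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  bad <- !(codes %in% c(0L, 1L, 2L) | (allow_missing & is.na(codes)))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(codes)), arr.ind = TRUE)[1, ]
    stop_ld("invalid genotype code %s at animal '%s', SNP '%s'",
            format(codes[idx[1], idx[2]]), animal_ids[idx[1]], snp_ids[idx[2]])
  }
  map <- as.data.frame(map)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop_ld("map must have columns: %s", paste(need, collapse = ", "))
  if (!setequal(map$snp_id, snp_ids))
    stop_ld("map snp_ids do not match matrix snp_ids")
  map <- map[match(snp_ids, map$snp_id), , drop = FALSE]
  rownames(map) <- NULL
  # normalize to genome order: chromosomes in order of first appearance,
  # positions ascending within chromosome (SNP order is canonical)
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos)
  if (!identical(ord, seq_along(ord))) {
    map <- map[ord, , drop = FALSE]
    rownames(map) <- NULL
    snp_ids <- snp_ids[ord]
    codes <- codes[, ord, drop = FALSE]
  }
  dimnames(codes) <- list(as.character(animal_ids), as.character(snp_ids))
  structure(list(codes = codes, animal_ids = as.character(animal_ids),
                 snp_ids = as.character(snp_ids), map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d SNP on %d chromosome(s)\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param animals animal ids (or indices) to keep; `NULL` keeps all.
#' @param snps SNP ids (or indices) to keep; `NULL` keeps all. Map order is
#'   preserved: the returned matrix keeps genome order, not request order.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, animals = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ai <- if (is.null(animals)) seq_along(x$animal_ids) else {
    if (is.character(animals)) {
      miss <- setdiff(animals, x$animal_ids)
      if (length(miss)) stop_ld("unknown animal id(s): %s",
                                paste(utils::head(miss, 5), collapse = ", "))
      match(animals, x$animal_ids)
    } else animals
  }
  si <- if (is.null(snps)) seq_along(x$snp_ids) else {
    if (is.character(snps)) {
      miss <- setdiff(snps, x$snp_ids)
      if (length(miss)) stop_ld("unknown snp id(s): %s",
                                paste(utils::head(miss, 5), collapse = ", "))
      sort(match(snps, x$snp_ids))
    } else sort(snps)
  }
  genotype_matrix(x$codes[ai, si, drop = FALSE], x$animal_ids[ai],
                  x$snp_ids[si], x$map[si, , drop = FALSE],
                  allow_missing = TRUE)
}

#' Cumulative genome coordinate of each SNP
#'
#' Chromosomes are concatenated in map order; the returned coordinate is
#' 0-based on the concatenated genome (position `pos` on a chromosome with
#' offset `o` maps to `o + pos - 1`). `chrom_lengths` may extend chromosome
#' ends beyond the last SNP; by default each chromosome's length is taken as
#' its largest mapped position.
#'
#' @param map SNP map data.frame (`snp_id`, `chrom`, `pos`).
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#' @return List with `coord` (per-SNP 0-based cumulative bp), `offsets`
#'   (named per-chromosome), `total_length`.
#' @export
genome_coordinates <- function(map, chrom_lengths = NULL) {
  chroms <- unique(map$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) max(map$pos[map$chrom == ch]),
                            numeric(1))
    names(chrom_lengths) <- chroms
  }
  if (!all(chroms %in% names(chrom_lengths)))
    stop_ld("chrom_lengths missing chromosome(s)")
  offsets <- cumsum(c(0, as.numeric(chrom_lengths[chroms])))[seq_along(chroms)]
  names(offsets) <- chroms
  coord <- offsets[as.character(map$chrom)] + map$pos - 1
  list(coord = unname(coord), offsets = offsets,
       total_length = sum(as.numeric(chrom_lengths[chroms])))
}
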