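# Low-density SNP subset construction.
#
# Four strategies: (1) the highest ranked SNP per trait; a single common
# subset of evenly spaced SNP choosing, per genome segment, the SNP best
# ranked for (2) ASI or (3) APR, or (4) the SNP with the highest minor
# allele frequency in the training set.

#' Minor allele frequencies in a training set
#'
#' @param X_training a `genotype_matrix` (complete genotypes).
#' @return Data.frame `snp_id`, `freq` (allele frequency of the counted
#'   allele, `sum(codes) / 2N`), `maf` (`min(f, 1 - f)`).
#' @export
compute_maf <- function(X_training) {
  M <- as_code_matrix(X_training)
  if (nrow(M) == 0) stop_ld("empty genotype matrix")
  if (anyNA(M)) stop_ld("missing genotypes; impute or filter first")
  f <- colSums(M) / (2 * nrow(M))
  ids <- if (inherits(X_training, "genotype_matrix")) X_training$snp_ids
         else colnames(M)
  data.frame(snp_id = ids, freq = as.numeric(f),
             maf = pmin(as.numeric(f), 1 - as.numeric(f)))
}

#' Partition the genome into equal-length segments
#'
#' Chromosomes are concatenated in map order onto a 0-based cumulative
#' coordinate of total length L; boundaries fall at `i * L / n`, giving n
#' half-open intervals of approximately equal bp length (segments may span
#' chromosome junctions).
#'
#' @param map SNP map (`snp_id`, `chrom`, `pos`).
#' @param n number of segments.
#' @param chrom_lengths optional named chromosome lengths (bp); defaults to
#'   the last mapped position per chromosome.
#' @return A `segment_partition`: `boundaries` data.frame (`segment`,
#'   `start`, `end`), `snp_segment` (per-SNP segment index aligned with the
#'   map), `total_length`, `n`.
#' @export
make_segments <- function(map, n, chrom_lengths = NULL) {
  if (n < 1) stop_ld("n must be >= 1")
  if (nrow(map) == 0) stop_ld("empty map")
  gc <- genome_coordinates(map, chrom_lengths)
  L <- gc$total_length
  edges <- L * (0:n) / n
  seg <- pmin(findInterval(gc$coord, edges, rightmost.closed = FALSE,
                           left.open = FALSE), n)
  if (n > nrow(map))
    warning(sprintf("more segments (%d) than SNP (%d); some will be empty",
                    n, nrow(map)))
  structure(list(
    boundaries = data.frame(segment = seq_len(n), start = edges[-(n + 1)],
                            end = edges[-1]),
    snp_segment = seg, coord = gc$coord, total_length = L, n = as.integer(n)),
    class = "segment_partition")
}

new_subset_spec <- function(strategy, n_requested, snp_ids, provenance) {
  structure(list(strategy = strategy, n_requested = as.integer(n_requested),
                 snp_ids = snp_ids, n_actual = length(snp_ids),
                 provenance = provenance),
            class = "subset_spec")
}

#' @export
print.subset_spec <- function(x, ...) {
  cat(sprintf("subset_spec [%s]: %d of %d requested SNP (%s)\n",
              x$strategy, x$n_actual, x$n_requested, x$provenance))
  invisible(x)
}

#' Select the top-ranked SNP for one trait
#'
#' Strategy 1: the subset is simply the first `n` entries of the trait's
#' backward-elimination ranking.
#'
#' @param ranked a `ranked_list`.
#' @param n subset size.
#' @return A `subset_spec`.
#' @export
select_top <- function(ranked, n) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (n > nrow(ranked$entries))
    stop_ld("n (%d) exceeds ranked SNP count (%d)", n, nrow(ranked$entries))
  ids <- ranked$entries$snp_id[seq_len(n)]
  new_subset_spec("trait_top", n, ids,
                  sprintf("top-ranked for %s (%s)", ranked$trait,
                          ranked$method))
}

#' Select evenly spaced SNP by rank or MAF
#'
#' Strategies 2-4: within each genome segment, pick the single SNP best
#' ranked for an index trait (a `ranked_list` criterion) or with the
#' highest training-set minor allele frequency (a MAF table criterion).
#' Empty segments contribute nothing; the shortfall is recorded in
#' `n_actual` (or optionally backfilled with the globally best unselected
#' SNP).
#'
#' Ties (equal rank cannot occur; equal MAF can) break by lower cumulative
#' genome coordinate.
#'
#' @param criterion a `ranked_list`, or a MAF data.frame from
#'   [compute_maf()].
#' @param segments a `segment_partition` built on the same map.
#' @param map the SNP map the segments were built on.
#' @param backfill if `TRUE`, empty-segment shortfall is filled with the
#'   best unselected SNP globally by the same criterion.
#' @return A `subset_spec` with `strategy` `"even_rank"` or `"even_maf"`.
#' @export
select_even <- function(criterion, segments, map, backfill = FALSE) {
  stopifnot(inherits(segments, "segment_partition"))
  seg_of <- segments$snp_segment
  coord <- segments$coord
  ids <- map$snp_id
  if (inherits(criterion, "ranked_list")) {
    score <- match(ids, criterion$entries$snp_id)  # smaller is better
    if (anyNA(score)) stop_ld("criterion ranking does not cover all map SNP")
    better <- function(a, b) a < b
    strat <- "even_rank"
    prov <- sprintf("rank for %s (%s)", criterion$trait, criterion$method)
  } else {
    mt <- as.data.frame(criterion)
    score <- mt$maf[match(ids, mt$snp_id)]
    if (anyNA(score)) stop_ld("MAF table does not cover all map SNP")
    score <- -score  # smaller is better
    better <- function(a, b) a < b
    strat <- "even_maf"
    prov <- "training-set MAF"
  }
  ord <- order(score, coord)  # best first; ties -> lower coordinate
  best_per_seg <- integer(0)
  seen <- logical(segments$n)
  for (i in ord) {
    s <- seg_of[i]
    if (!seen[s]) {
      seen[s] <- TRUE
      best_per_seg <- c(best_per_seg, i)
      if (all(seen)) break
    }
  }
  chosen <- ids[sort(best_per_seg)]
  shortfall <- segments$n - length(chosen)
  if (shortfall > 0) {
    ld_log("%d empty segment(s); subset short by %d SNP", shortfall, shortfall)
    if (backfill) {
      rest <- ord[!ids[ord] %in% chosen]
      chosen <- c(chosen, ids[rest[seq_len(min(shortfall, length(rest)))]])
    }
  }
  spec <- new_subset_spec(strat, segments$n, chosen, prov)
  spec$n_empty_segments <- shortfall
  spec
}

#' Cross-trait subset overlap
#'
#' For every combination of `k >= 2` traits, the percentage of SNP shared
#' by all subsets in the combination, relative to the requested subset
#' size; plus the mean percentage per combination size.
#'
#' @param subsets named list of `subset_spec`s, all with the same
#'   `n_requested`.
#' @param max_k largest combination size (default: all traits).
#' @return List: `combinations` (data.frame `k`, `traits`,
#'   `overlap_percent`), `by_k` (data.frame `k`, `mean_overlap_percent`).
#' @export
overlap_analysis <- function(subsets, max_k = length(subsets)) {
  if (length(subsets) < 2) stop_ld("need at least two subsets")
  ns <- vapply(subsets, function(s) s$n_requested, 1L)
  if (length(unique(ns)) != 1) stop_ld("subsets differ in n_requested")
  n_req <- ns[[1]]
  traits <- names(subsets)
  rows <- list()
  for (k in 2:max_k) {
    for (combo in utils::combn(traits, k, simplify = FALSE)) {
      inter <- Reduce(intersect, lapply(subsets[combo],
                                        function(s) s$snp_ids))
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, traits = paste(combo, collapse = "+"),
        overlap_percent = 100 * length(inter) / n_req)
    }
  }
  combos <- do.call(rbind, rows)
  by_k <- stats::aggregate(overlap_percent ~ k, combos, mean)
  names(by_k)[2] <- "mean_overlap_percent"
  list(combinations = combos, by_k = by_k)
}
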