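# Evaluation of DGV predictions: correlation accuracy, relative accuracy,
# pedigree relationship matrix (tabular method), and sire-in-training
# grouping of validation animals.

#' Accuracy of DGV as a correlation
#'
#' Pearson correlation between predicted DGV and the realized phenotype
#' (or the true breeding value in simulations). If either vector has zero
#' variance the correlation is undefined and `NA` is returned with a
#' warning rather than a fabricated 0.
#'
#' @param dgv,phenotype aligned numeric vectors, length >= 2.
#' @return Pearson correlation, or flagged `NA`.
#' @export
accuracy <- function(dgv, phenotype) {
  if (length(dgv) != length(phenotype))
    stop_ld("dgv and phenotype lengths differ")
  if (length(dgv) < 2) stop_ld("need at least 2 animals")
  if (stats::sd(dgv) == 0 || stats::sd(phenotype) == 0) {
    warning("zero variance; accuracy undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(dgv, phenotype)
}

#' Relative accuracy of a low-density subset
#'
#' Accuracy of a subset expressed as a percentage of the accuracy obtained
#' with the full high-density panel (same trait, same validation group).
#'
#' @param acc_subset subset accuracy.
#' @param acc_full full-panel accuracy; must be positive.
#' @return `100 * acc_subset / acc_full`, or flagged `NA` with a warning
#'   when the reference is not positive.
#' @export
relative_accuracy <- function(acc_subset, acc_full) {
  if (!is.finite(acc_full) || acc_full <= 0) {
    warning("full-panel accuracy not positive; relative accuracy undefined")
    return(NA_real_)
  }
  100 * acc_subset / acc_full
}

topo_order_pedigree <- function(ped) {
  # Kahn's algorithm; detects cycles (e.g. an animal being its own ancestor)
  ids <- ped$animal
  idx <- stats::setNames(seq_along(ids), ids)
  parents <- cbind(match(ped$sire, ids), match(ped$dam, ids))
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", length(ids))
  for (i in seq_along(ids)) for (pp in parents[i, ]) {
    if (!is.na(pp)) children[[pp]] <- c(children[[pp]], i)
  }
  queue <- which(indeg == 0)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids))
    stop_ld("pedigree contains a cycle involving: %s",
            paste(utils::head(ids[setdiff(seq_along(ids), out)], 5),
                  collapse = ", "))
  out
}

#' Additive-genetic relationship matrix (tabular method)
#'
#' Computes Wright's numerator relationship matrix by the tabular
#' recursion: `a(i, i) = 1 + a(sire_i, dam_i) / 2` and
#' `a(i, j) = (a(sire_i, j) + a(dam_i, j)) / 2` for `j` preceding `i`,
#' with unknown parents contributing 0. Inbreeding is carried through
#' the diagonal.
#'
#' @param pedigree data.frame with columns `animal`, `sire`, `dam`
#'   (`NA` = unknown parent). Parents referenced must appear as animals.
#' @param animals optional subset of ids for the returned matrix (the full
#'   recursion still runs over all their ancestors).
#' @return Symmetric numeric matrix with dimnames = animal ids.
#' @export
a_matrix <- function(pedigree, animals = NULL) {
  ped <- as.data.frame(pedigree)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop_ld("pedigree needs columns: %s", paste(need, collapse = ", "))
  refd <- stats::na.omit(unique(c(ped$sire, ped$dam)))
  unknown <- setdiff(refd, ped$animal)
  if (length(unknown))
    stop_ld("parent(s) not in pedigree: %s",
            paste(utils::head(unknown, 5), collapse = ", "))
  ord <- topo_order_pedigree(ped)
  ids <- ped$animal[ord]
  si <- match(ped$sire[ord], ids)
  di <- match(ped$dam[ord], ids)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      js <- seq_len(i - 1L)
      as_ <- if (is.na(s)) numeric(i - 1L) else A[js, s]
      ad_ <- if (is.na(d)) numeric(i - 1L) else A[js, d]
      A[js, i] <- A[i, js] <- (as_ + ad_) / 2
    }
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
  }
  if (!is.null(animals)) {
    miss <- setdiff(animals, ids)
    if (length(miss)) stop_ld("animal(s) not in pedigree: %s",
                              paste(utils::head(miss, 5), collapse = ", "))
    A <- A[animals, animals, drop = FALSE]
  }
  A
}

#' Split validation animals by sire representation in training
#'
#' @param validation_ids,training_ids animal id vectors.
#' @param pedigree data.frame covering the validation animals (`animal`,
#'   `sire`).
#' @return List `sire` (validation animals whose sire is a training
#'   animal) and `no_sire` (sire not in training, or unknown).
#' @export
group_by_sire <- function(validation_ids, training_ids, pedigree) {
  ped <- as.data.frame(pedigree)
  sires <- ped$sire[match(validation_ids, ped$animal)]
  if (any(is.na(match(validation_ids, ped$animal))))
    stop_ld("pedigree does not cover all validation animals")
  in_tr <- !is.na(sires) & sires %in% training_ids
  list(sire = validation_ids[in_tr], no_sire = validation_ids[!in_tr])
}

#' Assemble one evaluation result row
#'
#' @param trait,method,strategy,n_subset,group identification fields.
#' @param dgv,phenotype aligned vectors for the group.
#' @param acc_full full-panel accuracy for the same trait/group, used as
#'   the relative-accuracy reference (`NA` to skip).
#' @return One-row data.frame (`trait`, `method`, `strategy`, `n_subset`,
#'   `group`, `n_animals`, `accuracy`, `relative_accuracy`).
#' @export
evaluation_result <- function(trait, method, strategy, n_subset, group,
                              dgv, phenotype, acc_full = NA_real_) {
  n <- length(dgv)
  acc <- if (n >= 2) accuracy(dgv, phenotype) else {
    warning(sprintf("group '%s' has %d animal(s); accuracy undefined",
                    group, n))
    NA_real_
  }
  rel <- if (is.finite(acc_full) && is.finite(acc))
    suppressWarnings(relative_accuracy(acc, acc_full)) else NA_real_
  data.frame(trait = trait, method = method, strategy = strategy,
             n_subset = as.integer(n_subset), group = group,
             n_animals = as.integer(n), accuracy = acc,
             relative_accuracy = rel)
}

#' Summarize evaluation results across traits
#'
#' Mean relative accuracy across traits for each (strategy, subset size,
#' validation group), in the style of a low-density-assay summary table.
#' Groups with fewer than two animals are excluded.
#'
#' @param results data.frame of rows from [evaluation_result()].
#' @return Data.frame `method`, `strategy`, `n_subset`, `group`,
#'   `n_traits`, `mean_relative_accuracy`, `mean_accuracy`.
#' @export
summarize_results <- function(results) {
  res <- results[results$n_animals >= 2 & is.finite(results$accuracy), ,
                 drop = FALSE]
  dropped <- nrow(results) - nrow(res)
  if (dropped > 0)
    ld_log("excluded %d result row(s) with undefined accuracy", dropped)
  if (!nrow(res)) stop_ld("no valid results to summarize")
  key <- interaction(res$method, res$strategy, res$n_subset, res$group,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(res, key), function(g) {
    data.frame(method = g$method[1], strategy = g$strategy[1],
               n_subset = g$n_subset[1], group = g$group[1],
               n_traits = nrow(g),
               mean_relative_accuracy = mean(g$relative_accuracy),
               mean_accuracy = mean(g$accuracy))
  }))
  rownames(out) <- NULL
  out[order(out$method, out$strategy, out$n_subset, out$group), ,
      drop = FALSE]
}

#' Distribution summary of training-validation relationships
#'
#' Five-number summaries of the additive-genetic relationships between each
#' validation group and the training set (the box-and-whisker view of how
#' related validation animals are to the reference population).
#'
#' @param A relationship matrix from [a_matrix()].
#' @param training_ids,groups training ids and a named list of validation
#'   id groups.
#' @return Data.frame `group`, `n_pairs`, `min`, `q1`, `median`, `q3`,
#'   `max`, `mean` of the pairwise relationships.
#' @export
relationship_summary <- function(A, training_ids, groups) {
  do.call(rbind, lapply(names(groups), function(g) {
    idsv <- intersect(groups[[g]], rownames(A))
    idst <- intersect(training_ids, rownames(A))
    if (!length(idsv) || !length(idst))
      return(data.frame(group = g, n_pairs = 0L, min = NA, q1 = NA,
                        median = NA, q3 = NA, max = NA, mean = NA))
    vals <- as.numeric(A[idsv, idst, drop = FALSE])
    qs <- stats::quantile(vals, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(group = g, n_pairs = length(vals), min = qs[1], q1 = qs[2],
               median = qs[3], q3 = qs[4], max = qs[5], mean = mean(vals))
  }))
}
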