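# Backward-elimination SNP ranking.
#
# Starting from the full marker set, a model is fitted, markers are ranked
# by the absolute value of their regression coefficient, and the lowest
# ranked are dropped down to the next scheduled subset size. Coefficients
# are re-estimated (and the hyperparameter optionally re-tuned) at every
# step, because a marker's coefficient depends on the other markers in LD
# with it.

default_breakpoints <- function() {
  # (threshold, step): while the current size exceeds `threshold`, the next
  # size is current - step (aligned down to the rung grid).
  data.frame(threshold = c(10000, 1000, 300, 100),
             step = c(2000, 500, 100, 20))
}

schedule_rungs <- function(start, breakpoints, floor_size) {
  sizes <- start
  cur <- start
  while (cur > floor_size) {
    row <- which(cur > breakpoints$threshold)[1]
    if (is.na(row)) row <- nrow(breakpoints)
    step <- breakpoints$step[row]
    lower <- max(breakpoints$threshold[row], floor_size)
    nxt <- cur - step
    # land exactly on the rung grid of this band
    if (nxt < lower) nxt <- lower
    if ((cur - lower) %% step != 0 && nxt != lower)
      nxt <- lower + floor((cur - lower - 1) / step) * step
    sizes <- c(sizes, nxt)
    cur <- nxt
  }
  sizes
}

#' Build a backward-elimination subset-size schedule
#'
#' Default schedule: from the full marker count, first drop to 40,000
#' (when starting above that), then in steps of 2,000 while above 10,000,
#' steps of 500 while above 1,000, steps of 100 while above 300, and steps
#' of 20 down to the floor of 100. For smaller panels the schedule starts
#' at the largest rung at or below `p_total`.
#'
#' @param p_total total number of SNP (first schedule entry).
#' @param breakpoints data.frame with columns `threshold`, `step`
#'   (band lower bound and step size while above it); defaults to the
#'   schedule above.
#' @param first_drop size of the first retained set when `p_total` exceeds
#'   it (default 40,000; `NULL` disables the special first step).
#' @param floor_size smallest subset size (default 100).
#' @return A `schedule` object: strictly decreasing integer vector of
#'   subset sizes starting at `p_total`.
#' @examples
#' s <- make_schedule(42576)
#' s$sizes[2]  # 40000
#' @export
make_schedule <- function(p_total, breakpoints = NULL, first_drop = 40000,
                          floor_size = 100) {
  if (is.null(breakpoints)) breakpoints <- default_breakpoints()
  breakpoints <- breakpoints[order(-breakpoints$threshold), , drop = FALSE]
  if (p_total < floor_size)
    stop_ld(paste("p_total (%d) below the schedule floor (%d);",
                  "supply custom breakpoints/floor_size"),
            p_total, floor_size)
  if (!is.null(first_drop) && p_total > first_drop) {
    sizes <- c(p_total, schedule_rungs(first_drop, breakpoints, floor_size))
  } else {
    # start at the largest rung at or below p_total: each band's rung grid
    # is lower-bound + multiples of the band's step
    row <- which(p_total > breakpoints$threshold)[1]
    aligned <- if (!is.na(row)) {
      lower <- max(breakpoints$threshold[row], floor_size)
      lower + floor((p_total - lower) / breakpoints$step[row]) *
        breakpoints$step[row]
    } else floor_size
    sizes <- unique(c(p_total,
                      schedule_rungs(min(aligned, p_total), breakpoints,
                                     floor_size)))
  }
  sizes <- as.integer(sizes)
  stopifnot(all(diff(sizes) < 0))
  structure(list(sizes = sizes, p_total = as.integer(p_total)),
            class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("schedule: %d steps from %d down to %d SNP\n",
              length(x$sizes) - 1L, x$sizes[1], x$sizes[length(x$sizes)]))
  invisible(x)
}

fit_engine <- function(M, y, method, cv, hyperparameter = NULL,
                       weights = NULL) {
  if (method == "rr") {
    lam <- hyperparameter
    tune <- NULL
    if (is.null(lam)) {
      tune <- tune_lambda(M, y, cv, weights = weights)
      lam <- tune$lambda
    }
    fit <- solve_rr(M, y, lam, weights = weights)
    list(effects = fit, hyperparameter = lam,
         cv_score = if (is.null(tune)) NA_real_ else tune$score)
  } else {
    k <- hyperparameter
    tune <- NULL
    if (is.null(k)) {
      cv2 <- cv
      cv2$max_components <- min(cv$max_components, ncol(M), nrow(M) - 2L)
      tune <- tune_ncomp(M, y, cv2)
      k <- tune$n_components
    }
    fit <- suppressWarnings(fit_plsr(M, y, min(k, ncol(M), nrow(M) - 1L)))
    list(effects = fit$effects, hyperparameter = k,
         cv_score = if (is.null(tune)) NA_real_ else tune$score)
  }
}

#' Rank SNP by backward elimination
#'
#' Iterates the schedule: fit the model on the surviving SNP (re-tuning the
#' hyperparameter at each step unless a fixed value is given), rank by
#' absolute coefficient, retain the next scheduled number of SNP. SNP
#' dropped at a step receive ranks worse than all survivors, ordered among
#' themselves by their absolute coefficient at drop time; final survivors
#' are ranked by their final coefficients. Ties break by earlier genome
#' coordinate, then lexical SNP id.
#'
#' @param X a `genotype_matrix` of the training animals.
#' @param y training phenotype vector.
#' @param method `"rr"` or `"plsr"`.
#' @param schedule a `schedule`; defaults to `make_schedule(ncol(X))`.
#' @param cv a `cv_config`; the same `fold_seed` is reused at every step so
#'   fold membership stays constant along the elimination path.
#' @param hyperparameter optional fixed `lambda` / `n_components`;
#'   disables per-step re-tuning.
#' @param trait,weights label carried into the result; optional weights.
#' @param verbose log per-step progress.
#' @return A `ranked_list`: data.frame `entries` with columns `rank`,
#'   `snp_id`, `elimination_step`, `abs_coef`, plus `trait`, `method`,
#'   `steps` (per-step size, hyperparameter, CV score).
#' @export
backward_eliminate <- function(X, y, method = c("rr", "plsr"),
                               schedule = NULL, cv = cv_config(),
                               hyperparameter = NULL, trait = "trait",
                               weights = NULL, verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(X, "genotype_matrix"))
  p <- ncol(X$codes)
  if (is.null(schedule)) schedule <- make_schedule(p)
  if (schedule$sizes[1] != p)
    stop_ld("schedule starts at %d but X has %d SNP", schedule$sizes[1], p)
  coord <- genome_coordinates(X$map)$coord
  names(coord) <- X$snp_ids

  order_by_coef <- function(ids, abs_coef) {
    # descending |coef|; ties -> earlier genome coordinate, then id
    ids[order(-abs_coef, coord[ids], ids)]
  }

  alive <- X$snp_ids
  dropped <- list()  # per step, worst first overall ordering kept at end
  steps <- data.frame(size = integer(0), hyperparameter = numeric(0),
                      cv_score = numeric(0))
  sizes <- schedule$sizes
  final_fit <- NULL
  for (i in seq_along(sizes)) {
    Xi <- subset_genotypes(X, snps = alive)
    fit <- tryCatch(
      fit_engine(Xi, y, method, cv, hyperparameter, weights),
      error = function(e) stop_ld(
        "elimination step %d (size %d) failed: %s", i, length(alive),
        conditionMessage(e)))
    steps <- rbind(steps, data.frame(size = length(alive),
                                     hyperparameter = fit$hyperparameter,
                                     cv_score = fit$cv_score))
    ac <- abs(fit$effects$coefficients)
    ordered <- order_by_coef(names(ac), as.numeric(ac))
    if (i < length(sizes)) {
      keep_n <- sizes[i + 1L]
      keep <- ordered[seq_len(keep_n)]
      drop <- ordered[(keep_n + 1L):length(ordered)]
      dropped[[length(dropped) + 1L]] <-
        data.frame(snp_id = drop, elimination_step = i,
                   abs_coef = as.numeric(ac[drop]))
      alive <- keep
    } else {
      final_fit <- fit
      survivors <- data.frame(snp_id = ordered, elimination_step = NA_integer_,
                              abs_coef = as.numeric(ac[ordered]))
    }
    if (verbose)
      ld_log("step %d: size %d, hyperparameter %.4g", i,
             steps$size[nrow(steps)], fit$hyperparameter, verbose = TRUE)
  }
  # ranks: survivors best, then dropped batches from last-dropped to first
  entries <- rbind(survivors, do.call(rbind, rev(dropped)))
  entries$rank <- seq_len(nrow(entries))
  entries <- entries[, c("rank", "snp_id", "elimination_step", "abs_coef")]
  rownames(entries) <- NULL
  structure(list(trait = trait, method = method, entries = entries,
                 steps = steps, final_effects = final_fit$effects),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("ranked_list [%s, %s]: %d SNP in %d elimination step(s)\n",
              x$trait, x$method, nrow(x$entries), nrow(x$steps)))
  invisible(x)
}
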