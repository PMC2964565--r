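# Univariate partial least squares regression, orthogonal-scores
# (NIPALS-style) algorithm with X-only deflation. For a single response
# this is equivalent to SIMPLS. Latent components t = X w maximize
# covariance with y and are mutually orthogonal by construction.

#' Fit partial least squares regression
#'
#' Extracts `n_components` orthogonal latent components from the centered
#' genotype matrix, each a linear combination `t = X w` with maximal
#' covariance with the (centered) response, deflating X after each
#' component. Regression coefficients are back-transformed to the raw
#' 0/1/2 dosage scale, with the centering absorbed into the intercept.
#'
#' @param X a `genotype_matrix` or numeric matrix (N x p).
#' @param y numeric response, length N.
#' @param n_components number of latent components,
#'   `1 <= n_components <= min(N - 1, p)`.
#' @param keep_path if `TRUE`, also return the coefficient path
#'   (`coef_path`: p x k matrix of coefficients for models with 1..k
#'   components) — used by the cross-validation tuner.
#' @return List: `effects` (a `marker_effects`) and `decomposition`
#'   (`scores` N x k, `weights` p x k, `loadings` p x k,
#'   `n_components_achieved`). Extraction stops early with a warning if X
#'   is exhausted before `n_components` components.
#' @examples
#' X <- matrix(c(0, 1, 2), 3, 1)
#' fit_plsr(X, c(1, 2, 4), 1)$effects  # slope 1.5, intercept 5/6
#' @export
fit_plsr <- function(X, y, n_components, keep_path = FALSE) {
  M <- as_code_matrix(X)
  storage.mode(M) <- "double"
  n <- nrow(M)
  p <- ncol(M)
  if (length(y) != n) stop_ld("y length (%d) != animals (%d)", length(y), n)
  kmax <- min(n - 1L, p)
  if (n_components < 1 || n_components > kmax)
    stop_ld("n_components must lie in [1, %d]", kmax)
  xbar <- colMeans(M)
  ybar <- mean(y)
  E <- sweep(M, 2, xbar)
  f <- y - ybar
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  achieved <- 0L
  x_scale <- sqrt(sum(E^2))
  for (k in seq_len(n_components)) {
    w <- as.numeric(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12 * max(x_scale, 1) || sqrt(sum(E^2)) < 1e-12 * max(x_scale, 1)) {
      warning(sprintf("X exhausted after %d component(s); requested %d",
                      achieved, n_components))
      break
    }
    w <- w / wn
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24 * max(x_scale, 1)^2) {
      warning(sprintf("degenerate score at component %d; stopping", k))
      break
    }
    pl <- as.numeric(crossprod(E, t)) / tt
    q[k] <- sum(f * t) / tt
    E <- E - tcrossprod(t, pl)
    W[, k] <- w
    P[, k] <- pl
    Tm[, k] <- t
    achieved <- k
  }
  if (achieved == 0L) stop_ld("no PLSR component could be extracted")
  W <- W[, seq_len(achieved), drop = FALSE]
  P <- P[, seq_len(achieved), drop = FALSE]
  Tm <- Tm[, seq_len(achieved), drop = FALSE]
  q <- q[seq_len(achieved)]
  # b = W (P'W)^-1 q
  R <- crossprod(P, W)
  coef_for <- function(k) {
    qs <- solve(R[seq_len(k), seq_len(k), drop = FALSE], q[seq_len(k)])
    as.numeric(W[, seq_len(k), drop = FALSE] %*% qs)
  }
  b <- coef_for(achieved)
  snp_ids <- if (inherits(X, "genotype_matrix")) X$snp_ids else colnames(M)
  names(b) <- snp_ids
  eff <- marker_effects(method = "plsr", intercept = ybar - sum(xbar * b),
                        coefficients = b, hyperparameter = achieved,
                        centering = stats::setNames(xbar, snp_ids))
  out <- list(effects = eff,
              decomposition = list(scores = Tm, weights = W, loadings = P,
                                   n_components_achieved = achieved))
  if (keep_path) {
    cp <- vapply(seq_len(achieved), coef_for, numeric(p))
    out$coef_path <- matrix(cp, p, achieved)
    out$xbar <- xbar
    out$ybar <- ybar
  }
  out
}

#' Tune the number of PLSR components by cross-validation
#'
#' Evaluates 1..`max_components` latent components on a fixed k-fold
#' assignment and returns the count minimizing mean CV MSE (or maximizing
#' mean CV correlation). Ties go to the smaller count.
#'
#' @param X a `genotype_matrix` or numeric matrix.
#' @param y response vector.
#' @param cv a `cv_config` (`max_components`, `k_folds`, `fold_seed`,
#'   `objective`).
#' @return List: `n_components`, `score`, `profile` (data.frame of
#'   `(n_components, score)`), `folds`.
#' @export
tune_ncomp <- function(X, y, cv = cv_config()) {
  M <- as_code_matrix(X)
  storage.mode(M) <- "double"
  n <- nrow(M)
  folds <- make_folds(n, cv$k_folds, cv$fold_seed)
  kmax <- cv$max_components
  kmax <- min(kmax, ncol(M))
  score_mat <- matrix(NA_real_, cv$k_folds, kmax)
  for (f in seq_len(cv$k_folds)) {
    tr <- folds != f
    k_f <- min(kmax, sum(tr) - 1L)
    fit <- suppressWarnings(
      fit_plsr(M[tr, , drop = FALSE], y[tr], k_f, keep_path = TRUE))
    ach <- fit$decomposition$n_components_achieved
    Ete <- sweep(M[!tr, , drop = FALSE], 2, fit$xbar)
    for (k in seq_len(min(ach, kmax))) {
      pred <- fit$ybar + as.numeric(Ete %*% fit$coef_path[, k])
      score_mat[f, k] <- if (cv$objective == "mse") {
        mean((y[!tr] - pred)^2)
      } else {
        if (stats::sd(pred) == 0 || stats::sd(y[!tr]) == 0) NA_real_
        else -stats::cor(pred, y[!tr])
      }
    }
  }
  mean_scores <- colMeans(score_mat, na.rm = TRUE)
  if (all(!is.finite(mean_scores))) stop_ld("objective non-finite for all k")
  best <- which.min(mean_scores)  # ties -> smallest k
  list(n_components = as.integer(best), score = mean_scores[best],
       profile = data.frame(n_components = seq_len(kmax),
                            score = mean_scores),
       folds = folds)
}
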