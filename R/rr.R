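# SNP-BLUP ridge regression solved on the mixed model equations
#
#   [ 1'W1   1'WX      ] [mu]   [1'Wy]
#   [ X'W1   X'WX + I*l] [b ] = [X'Wy]
#
# with W an optional diagonal weight matrix (identity by default). The
# system is solved matrix-free by a Jacobi-preconditioned conjugate
# gradient: only products with X and X' are formed, never X'X, so memory
# stays O(Np + p).

as_code_matrix <- function(X) {
  if (inherits(X, "genotype_matrix")) X$codes else as.matrix(X)
}

mme_matvec <- function(M, w, lambda, v) {
  # v = c(mu, b); returns C %*% v for the (weighted) MME coefficient matrix
  mu <- v[1]
  b <- v[-1]
  fit <- mu + as.numeric(M %*% b)
  wfit <- w * fit
  c(sum(wfit), as.numeric(crossprod(M, wfit)) + lambda * b)
}

#' Fit SNP-BLUP ridge regression
#'
#' Estimates an intercept and one shrunken effect per SNP by solving the
#' mixed model equations with a common penalty `lambda` on every SNP
#' (equivalent to BLUP of marker effects under a common normal prior, where
#' `lambda = sigma2_e / sigma2_b`). Genotypes enter as raw 0/1/2 dosages
#' with an explicit intercept; no column centering is applied.
#'
#' @param X a `genotype_matrix` or numeric matrix (N x p dosages).
#' @param y numeric phenotype vector, length N, aligned with rows of `X`.
#' @param lambda ridge penalty, `> 0`.
#' @param weights optional per-animal positive weights (e.g. daughter
#'   counts); default all 1.
#' @param tol relative residual tolerance of the conjugate-gradient solver
#'   (tight by default so the solution matches a direct solve to well below
#'   practical precision needs).
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   residual history.
#' @return A `marker_effects` object: `method = "rr"`, `intercept`,
#'   `coefficients` (named by SNP id when available), `hyperparameter`
#'   (`lambda`), `iterations`, `residual`.
#' @examples
#' X <- matrix(c(0, 2), 2, 1)
#' solve_rr(X, c(-1, 1), lambda = 2)  # intercept -0.5, coefficient 0.5
#' @export
solve_rr <- function(X, y, lambda, weights = NULL, tol = 1e-11,
                     max_iter = 5000L) {
  M <- as_code_matrix(X)
  storage.mode(M) <- "double"
  n <- nrow(M)
  p <- ncol(M)
  if (n < 2 || p < 1) stop_ld("need N >= 2 animals and p >= 1 SNP")
  if (length(y) != n) stop_ld("y length (%d) != animals (%d)", length(y), n)
  if (!is.finite(lambda) || lambda <= 0) stop_ld("lambda must be > 0")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w <= 0)) stop_ld("weights must be positive, length N")

  rhs <- c(sum(w * y), as.numeric(crossprod(M, w * y)))
  # Jacobi preconditioner: diagonal of the MME
  diag_mme <- c(sum(w), as.numeric(crossprod(M^2, w)) + lambda)
  theta <- numeric(p + 1L)
  r <- rhs - mme_matvec(M, w, lambda, theta)
  z <- r / diag_mme
  d <- z
  rhs_norm <- sqrt(sum(rhs^2))
  if (rhs_norm == 0) rhs_norm <- 1
  rz <- sum(r * z)
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    res <- sqrt(sum(r^2)) / rhs_norm
    hist <- c(hist, res)
    if (res <= tol) break
    Cd <- mme_matvec(M, w, lambda, d)
    alpha <- rz / sum(d * Cd)
    theta <- theta + alpha * d
    r <- r - alpha * Cd
    z <- r / diag_mme
    rz_new <- sum(r * z)
    d <- z + (rz_new / rz) * d
    rz <- rz_new
    if (it == max_iter && sqrt(sum(r^2)) / rhs_norm > tol) {
      err <- simpleError(sprintf(
        "PCG did not converge in %d iterations (relative residual %.3g)",
        max_iter, sqrt(sum(r^2)) / rhs_norm))
      err$residual_history <- hist
      stop(err)
    }
  }
  coef <- theta[-1]
  names(coef) <- if (inherits(X, "genotype_matrix")) X$snp_ids else colnames(M)
  marker_effects(method = "rr", intercept = theta[1], coefficients = coef,
                 hyperparameter = lambda,
                 extra = list(iterations = it, residual = utils::tail(hist, 1),
                              weighted = !is.null(weights)))
}

#' Cross-validation configuration
#'
#' @param k_folds number of folds (>= 2).
#' @param objective `"mse"` (mean squared prediction error, minimized) or
#'   `"correlation"` (predictive correlation, maximized).
#' @param fold_seed integer seed making the fold assignment a deterministic
#'   function of animal order.
#' @param lambda_bracket search bracket for the ridge penalty; `NULL`
#'   defaults to `c(1e-3, 1e3) * p` at tuning time.
#' @param gs_tolerance relative tolerance of the golden-section search on
#'   `log10(lambda)`.
#' @param max_components largest PLSR component count evaluated.
#' @return A `cv_config` object.
#' @export
cv_config <- function(k_folds = 10L, objective = c("mse", "correlation"),
                      fold_seed = 1L, lambda_bracket = NULL,
                      gs_tolerance = 1e-2, max_components = 20L) {
  objective <- match.arg(objective)
  if (k_folds < 2) stop_ld("k_folds must be >= 2")
  if (!is.null(lambda_bracket) && lambda_bracket[1] > lambda_bracket[2])
    stop_ld("lambda bracket low > high")
  structure(list(k_folds = as.integer(k_folds), objective = objective,
                 fold_seed = as.integer(fold_seed),
                 lambda_bracket = lambda_bracket,
                 gs_tolerance = gs_tolerance,
                 max_components = as.integer(max_components)),
            class = "cv_config")
}

#' Deterministic fold assignment
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param fold_seed integer seed.
#' @return Integer vector of fold labels in `1..k`, a deterministic function
#'   of `(n, k, fold_seed)`.
#' @export
make_folds <- function(n, k, fold_seed) {
  if (n < k) stop_ld("fewer observations (%d) than folds (%d)", n, k)
  with_seed(fold_seed, sample(rep_len(seq_len(k), n)))
}

#' Golden-section search for a scalar minimum
#'
#' Minimizes a unimodal function on a bracket to a relative tolerance.
#' Used on `log10(lambda)` for ridge tuning; exposed so alternative
#' objectives can be plugged in.
#'
#' @param fn objective function of one scalar.
#' @param lower,upper bracket; a zero-width bracket returns it immediately.
#' @param tol relative tolerance on the argument.
#' @param max_iter safety cap.
#' @return List: `minimum` (argmin), `objective` (value there), and
#'   `evaluations` (data.frame of all evaluated points).
#' @export
golden_section <- function(fn, lower, upper, tol = 1e-2, max_iter = 200L) {
  if (lower > upper) stop_ld("invalid bracket: lower > upper")
  evals <- data.frame(x = numeric(0), value = numeric(0))
  track <- function(x) {
    v <- fn(x)
    evals <<- rbind(evals, data.frame(x = x, value = v))
    v
  }
  if (lower == upper)
    return(list(minimum = lower, objective = track(lower),
                evaluations = evals))
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- track(x1); f2 <- track(x2)
  scale <- max(abs(a), abs(b), 1)
  for (i in seq_len(max_iter)) {
    if ((b - a) <= tol * scale) break
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a)
      f1 <- track(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a)
      f2 <- track(x2)
    }
  }
  xbest <- if (f1 <= f2) x1 else x2
  list(minimum = xbest, objective = min(f1, f2), evaluations = evals)
}

cv_score_rr <- function(M, y, lambda, folds, k, objective, weights,
                        tol, max_iter) {
  scores <- numeric(0)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- solve_rr(M[tr, , drop = FALSE], y[tr], lambda,
                    weights = if (is.null(weights)) NULL else weights[tr],
                    tol = tol, max_iter = max_iter)
    pred <- fit$intercept +
      as.numeric(M[!tr, , drop = FALSE] %*% fit$coefficients)
    s <- if (objective == "mse") {
      mean((y[!tr] - pred)^2)
    } else {
      if (stats::sd(pred) == 0 || stats::sd(y[!tr]) == 0) {
        warning("constant predictions in a fold; fold skipped")
        NA_real_
      } else -stats::cor(pred, y[!tr])
    }
    scores <- c(scores, s)
  }
  if (all(is.na(scores))) stop_ld("objective non-finite on every fold")
  mean(scores, na.rm = TRUE)
}

#' Tune the ridge penalty by cross-validation
#'
#' Runs a golden-section search on `log10(lambda)` over the bracket,
#' scoring each candidate by k-fold cross-validation on a fixed fold
#' assignment (common random numbers across candidates).
#'
#' @param X a `genotype_matrix` or numeric matrix.
#' @param y phenotype vector.
#' @param cv a `cv_config`; `lambda_bracket = NULL` defaults to
#'   `c(1e-3, 1e3) * ncol(X)`.
#' @param weights optional per-animal weights passed through to the fits.
#' @param tol,max_iter solver controls for the inner fits.
#' @return List: `lambda` (the selected penalty), `score` (its CV score,
#'   MSE or negative correlation), `profile` (data.frame of evaluated
#'   `(lambda, score)` pairs), `folds`.
#' @export
tune_lambda <- function(X, y, cv = cv_config(), weights = NULL,
                        tol = 1e-8, max_iter = 5000L) {
  M <- as_code_matrix(X)
  storage.mode(M) <- "double"
  bracket <- cv$lambda_bracket %||% (c(1e-3, 1e3) * ncol(M))
  if (any(bracket <= 0)) stop_ld("lambda bracket must be positive")
  folds <- make_folds(nrow(M), cv$k_folds, cv$fold_seed)
  fn <- function(loglam)
    cv_score_rr(M, y, 10^loglam, folds, cv$k_folds, cv$objective,
                weights, tol, max_iter)
  gs <- golden_section(fn, log10(bracket[1]), log10(bracket[2]),
                       tol = cv$gs_tolerance)
  profile <- data.frame(lambda = 10^gs$evaluations$x,
                        score = gs$evaluations$value)
  list(lambda = 10^gs$minimum, score = gs$objective, profile = profile,
       folds = folds)
}
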