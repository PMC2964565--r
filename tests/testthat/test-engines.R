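# Ridge regression (PCG on the mixed model equations) and PLSR engines,
# hyperparameter tuning, and DGV prediction.

test_that("PCG reproduces the hand-solved 2x2 mixed model equations", {
  X <- matrix(c(0, 2), 2, 1)
  fit <- solve_rr(X, c(-1, 1), lambda = 2)
  expect_equal(fit$intercept, -0.5, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), 0.5, tolerance = 1e-8)
  expect_equal(unname(predict_dgv(X, fit)), c(0, 1), tolerance = 1e-8)
})

test_that("PCG matches a dense direct solve on random instances", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    p <- sample(1:500, 1)
    lambda <- 10^runif(1, -2, 3)
    X <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
    y <- rnorm(n)
    theta <- dense_mme_solve(X, y, lambda)
    fit <- solve_rr(X, y, lambda)
    expect_lt(max(abs(c(fit$intercept, fit$coefficients) - theta)), 1e-6)
  }
})

test_that("weighted ridge matches a weighted dense solve", {
  set.seed(3)
  X <- matrix(sample(0:2, 40 * 15, TRUE), 40, 15)
  y <- rnorm(40)
  w <- runif(40, 0.5, 4)
  theta <- dense_mme_solve(X, y, 5, w)
  fit <- solve_rr(X, y, 5, weights = w)
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - theta)), 1e-6)
})

test_that("extreme penalties give the shrinkage and OLS limits", {
  set.seed(4)
  X <- matrix(sample(0:2, 60 * 5, TRUE), 60, 5)
  y <- rnorm(60)
  big <- solve_rr(X, y, 1e12)
  expect_lt(max(abs(big$coefficients)), 1e-6)
  expect_equal(big$intercept, mean(y), tolerance = 1e-4)
  # lambda -> 0 on overdetermined full-rank X approaches OLS
  small <- solve_rr(X, y, 1e-8 * ncol(X), tol = 1e-10)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(c(small$intercept, small$coefficients)), unname(ols),
               tolerance = 1e-4)
})

test_that("invalid ridge inputs are rejected", {
  X <- matrix(sample(0:2, 20, TRUE), 10, 2)
  expect_error(solve_rr(X, rnorm(10), lambda = 0), "lambda")
  expect_error(solve_rr(X, rnorm(9), 1), "length")
  e <- tryCatch(solve_rr(X, rnorm(10), 1, max_iter = 1L, tol = 1e-14),
                error = identity)
  expect_s3_class(e, "error")
  expect_true(length(e$residual_history) >= 1)
})

test_that("golden-section search finds an analytic minimum", {
  fn <- function(x) (x - log10(3))^2
  gs <- golden_section(fn, log10(0.01), log10(1000), tol = 1e-4)
  expect_equal(10^gs$minimum, 3, tolerance = 0.01)
  # degenerate zero-width bracket returns immediately
  gs0 <- golden_section(fn, 2, 2)
  expect_equal(gs0$minimum, 2)
  expect_equal(nrow(gs0$evaluations), 1L)
})

test_that("tuned lambda beats the bracket endpoints and is reproducible", {
  set.seed(10)
  n <- 120; p <- 60
  X <- matrix(sample(0:2, n * p, TRUE), n, p)
  b <- rnorm(p, 0, sqrt(1 / p))
  y <- as.numeric(X %*% b) + rnorm(n, 0, 1)
  cv <- cv_config(k_folds = 5, fold_seed = 7, gs_tolerance = 1e-2)
  tl <- tune_lambda(X, y, cv)
  ends <- vapply(c(1e-3, 1e3) * p, function(l)
    ldpanel:::cv_score_rr(X, y, l, tl$folds, 5, "mse", NULL, 1e-8, 5000),
    numeric(1))
  expect_lte(tl$score, min(ends) + 1e-12)
  tl2 <- tune_lambda(X, y, cv)
  expect_identical(tl$lambda, tl2$lambda)
  expect_identical(tl$folds, tl2$folds)
})

test_that("PLSR with one SNP equals the simple least-squares line", {
  fit <- fit_plsr(matrix(c(0, 1, 2), 3, 1), c(1, 2, 4), 1)
  expect_equal(unname(fit$effects$coefficients), 1.5, tolerance = 1e-10)
  expect_equal(fit$effects$intercept, 5 / 6, tolerance = 1e-10)
})

test_that("saturated PLSR reproduces OLS and scores are orthogonal", {
  set.seed(11)
  X <- matrix(sample(0:2, 30 * 4, TRUE), 30, 4)
  y <- rnorm(30)
  k <- qr(scale(X, scale = FALSE))$rank
  fit <- fit_plsr(X, y, k)
  pred <- predict_response(X, fit$effects)
  expect_equal(pred, unname(fitted(lm(y ~ X))), tolerance = 1e-8)
  Tm <- fit$decomposition$scores
  for (i in seq_len(ncol(Tm) - 1)) for (j in (i + 1):ncol(Tm))
    expect_lt(abs(sum(Tm[, i] * Tm[, j])),
              1e-10 * sqrt(sum(Tm[, i]^2) * sum(Tm[, j]^2)))
})

test_that("PLSR stops early when X is exhausted", {
  X <- matrix(c(0, 1, 2, 0, 2, 4), 3, 2)  # rank-1 after centering
  expect_warning(fit <- fit_plsr(X, c(1, 2, 3), 2), "exhausted|component")
  expect_equal(fit$decomposition$n_components_achieved, 1L)
})

test_that("component-count tuning recovers a rank-1 signal and the argmin", {
  set.seed(12)
  n <- 80; p <- 40
  # rank-one predictor structure: a single latent direction generates both
  # X and y exactly, in every cross-validation fold
  tvec <- rnorm(n)
  load <- rnorm(p)
  X <- tcrossprod(tvec, load)
  y <- tvec
  cv <- cv_config(k_folds = 5, fold_seed = 2, max_components = 6)
  tk <- tune_ncomp(X, y, cv)
  expect_equal(tk$n_components, 1L)
  # argmin property on noise
  y2 <- rnorm(n)
  tk2 <- tune_ncomp(X, y2, cv)
  expect_equal(tk2$score, min(tk2$profile$score, na.rm = TRUE))
  # max_components = 1 returns 1
  expect_equal(tune_ncomp(X, y2, cv_config(k_folds = 5, fold_seed = 2,
                                           max_components = 1))$n_components,
               1L)
})

test_that("predictions are invariant to SNP column order", {
  g <- random_genotypes(40, 25, seed = 13)
  set.seed(13)
  y <- rnorm(40)
  fit_rr <- solve_rr(g, y, 10)
  fit_pl <- fit_plsr(g, y, 3)$effects
  perm <- sample(25)
  gp <- genotype_matrix(g$codes[, perm], g$animal_ids, g$snp_ids[perm],
                        g$map[perm, ])
  expect_equal(predict_dgv(gp, fit_rr), predict_dgv(g, fit_rr))
  expect_equal(predict_dgv(gp, fit_pl), predict_dgv(g, fit_pl))
})

test_that("DGV prediction validates SNP sets and handles zero effects", {
  g <- random_genotypes(10, 5, seed = 14)
  set.seed(14)
  fit <- solve_rr(g, rnorm(10), 1)
  g2 <- subset_genotypes(g, snps = g$snp_ids[1:4])
  expect_error(predict_dgv(g2, fit), "mismatch")
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_true(all(predict_dgv(g, fit0) == 0))
})

test_that("training accuracy is not below validation accuracy on average", {
  d <- vapply(1:10, function(s) {
    pop <- small_population(seed = 100 + s)
    sp <- split_sets(pop)
    ph <- simulate_phenotypes(pop, "t1")
    y <- setNames(ph$value, ph$animal_id)
    Xtr <- subset_genotypes(pop$genotypes, animals = sp$training_ids)
    Xva <- subset_genotypes(pop$genotypes, animals = sp$validation_ids)
    fit <- solve_rr(Xtr, y[sp$training_ids], lambda = ncol(Xtr$codes) / 10)
    acc_tr <- accuracy(predict_dgv(Xtr, fit), y[sp$training_ids])
    acc_va <- accuracy(predict_dgv(Xva, fit), y[sp$validation_ids])
    acc_tr - acc_va
  }, numeric(1))
  expect_gt(mean(d), 0)
})
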