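# Backward-elimination ranking and the subset-size schedule.

test_that("default schedule reproduces the published subset sizes", {
  s <- make_schedule(42576)
  expect_equal(s$sizes[1], 42576L)
  expect_equal(s$sizes[2], 40000L)
  expect_true(all(c(100, 300, 500, 1000, 3000, 5000) %in% s$sizes))
  expect_true(all(diff(s$sizes) < 0))
  expect_equal(min(s$sizes), 100L)
  # band structure: drops of 2000 above 10k, 500 above 1k, 100 above 300,
  # 20 above 100
  d <- -diff(s$sizes)
  sz <- s$sizes[-1]
  expect_true(all(d[sz >= 10000][-1] == 2000))
  expect_true(all(d[sz < 10000 & sz >= 1000] == 500))
  expect_true(all(d[sz < 1000 & sz >= 300] == 100))
  expect_true(all(d[sz < 300] == 20))
})

test_that("small panels start at the largest rung at or below p", {
  s <- make_schedule(1000)
  expect_equal(s$sizes[1:3], c(1000L, 900L, 800L))
  expect_true(all(c(300, 280, 100) %in% s$sizes))
  expect_equal(length(s$sizes), 18L)
  s2 <- make_schedule(2345)
  expect_equal(s2$sizes[2], 2000L)
  expect_error(make_schedule(50), "floor")
  expect_equal(make_schedule(250, breakpoints = data.frame(threshold = 50,
                                                           step = 100),
                             floor_size = 50)$sizes,
               c(250L, 150L, 50L))
})

test_that("elimination yields a contiguous permutation respecting the schedule", {
  g <- random_genotypes(30, 5, seed = 20)
  set.seed(20)
  y <- rnorm(30)
  sched <- make_schedule(5, breakpoints = data.frame(threshold = 1, step = 2),
                         first_drop = NULL, floor_size = 1)
  expect_equal(sched$sizes, c(5L, 3L, 1L))
  rk <- backward_eliminate(g, y, "rr", sched, hyperparameter = 2)
  expect_setequal(rk$entries$snp_id, g$snp_ids)
  expect_identical(rk$entries$rank, 1:5)
  expect_equal(rk$steps$size, c(5L, 3L, 1L))
  # survivors of step i equal the scheduled size
  expect_equal(sum(is.na(rk$entries$elimination_step)), 1L)
  expect_equal(sum(rk$entries$elimination_step == 2, na.rm = TRUE), 2L)
  expect_equal(sum(rk$entries$elimination_step == 1, na.rm = TRUE), 2L)
})

test_that("with fixed lambda the first drop equals the bottom of a full fit", {
  g <- random_genotypes(60, 30, seed = 21)
  set.seed(21)
  y <- rnorm(60)
  sched <- make_schedule(30, breakpoints = data.frame(threshold = 10,
                                                      step = 10),
                         first_drop = NULL, floor_size = 10)
  rk <- backward_eliminate(g, y, "rr", sched, hyperparameter = 7)
  full <- solve_rr(g, y, 7)
  bottom <- names(sort(abs(full$coefficients)))[1:10]
  dropped1 <- rk$entries$snp_id[rk$entries$elimination_step == 1 &
                                  !is.na(rk$entries$elimination_step)]
  expect_setequal(dropped1, bottom)
})

test_that("ranking is deterministic and order-invariant", {
  g <- random_genotypes(50, 20, seed = 22)
  set.seed(22)
  y <- rnorm(50)
  sched <- make_schedule(20, breakpoints = data.frame(threshold = 5, step = 5),
                         first_drop = NULL, floor_size = 5)
  cv <- cv_config(k_folds = 5, fold_seed = 3)
  rk1 <- backward_eliminate(g, y, "rr", sched, cv)
  rk2 <- backward_eliminate(g, y, "rr", sched, cv)
  expect_identical(rk1$entries, rk2$entries)
  perm <- sample(20)
  gp <- genotype_matrix(g$codes[, perm], g$animal_ids, g$snp_ids[perm],
                        g$map[perm, ])
  rk3 <- backward_eliminate(gp, y, "rr", sched, cv)
  expect_identical(rk3$entries$snp_id, rk1$entries$snp_id)
})

test_that("a planted large-effect SNP is ranked to the top", {
  hits <- vapply(1:6, function(s) {
    set.seed(300 + s)
    n <- 150; p <- 101
    X <- matrix(rbinom(n * p, 2, 0.3), n, p)
    beta <- sqrt(0.5 / var(X[, 51]))   # planted SNP: 50% of genetic variance
    g_part <- X[, 51] * beta
    y <- g_part + rnorm(n, 0, sd(g_part))
    map <- data.frame(snp_id = sprintf("s%03d", 1:p), chrom = 1,
                      pos = seq_len(p) * 1000)
    gm <- genotype_matrix(X, sprintf("a%03d", 1:n), map$snp_id, map)
    sched <- make_schedule(p, breakpoints = data.frame(threshold = 20,
                                                       step = 40),
                           first_drop = NULL, floor_size = 20)
    rk <- backward_eliminate(gm, y, "rr", sched,
                             cv = cv_config(k_folds = 5, fold_seed = 1))
    match("s051", rk$entries$snp_id) <= 20
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("plsr-based elimination also produces a valid ranking", {
  g <- random_genotypes(40, 15, seed = 23)
  set.seed(23)
  y <- rnorm(40)
  sched <- make_schedule(15, breakpoints = data.frame(threshold = 5, step = 5),
                         first_drop = NULL, floor_size = 5)
  rk <- backward_eliminate(g, y, "plsr", sched,
                           cv = cv_config(k_folds = 4, fold_seed = 5,
                                          max_components = 4))
  expect_setequal(rk$entries$snp_id, g$snp_ids)
  expect_identical(rk$entries$rank, seq_len(15L))
  expect_identical(rk$method, "plsr")
})
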