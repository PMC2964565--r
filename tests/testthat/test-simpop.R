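# Population simulator: pedigree structure, Mendelian transmission,
# variance calibration, LD generation, phenotype noise model.

test_that("simulated pedigrees are structurally valid", {
  pop <- small_population(seed = 11)
  ped <- pop$pedigree
  non_f <- ped[!is.na(ped$sire) & !is.na(ped$dam), ]
  parent_years <- ped$birth_year[match(non_f$sire, ped$animal)]
  expect_true(all(parent_years < non_f$birth_year))
  expect_true(all(pop$genotypes$codes %in% 0:2))
  expect_identical(check_mendelian(pop), 0L)
})

test_that("null architecture (sigma2_g = 0) gives all-zero TBV", {
  pop <- small_population(seed = 3, sigma2_g = 0)
  expect_true(all(pop$tbv == 0))
})

test_that("TBV variance is calibrated to sigma2_g among founders", {
  cfg <- simulation_config(n_founders = 600, n_generations = 1,
                           n_chromosomes = 2, snp_per_chrom = 50,
                           n_qtl = 1, major_gene_fraction = 0,
                           sigma2_g = 2.5, h2 = 0.4, n_burnin = 5,
                           burnin_size = 80, seed = 5)
  pop <- simulate_population(cfg)
  v <- var(pop$tbv[pop$pedigree$generation == 0, 1])
  expect_gt(v / 2.5, 0.8)
  expect_lt(v / 2.5, 1.2)
})

test_that("major-gene architecture assigns the stated variance share", {
  cfg <- simulation_config(n_founders = 500, n_generations = 1,
                           n_chromosomes = 2, snp_per_chrom = 100,
                           n_qtl = 40, major_gene_fraction = 0.3,
                           sigma2_g = 1, h2 = 0.5, n_burnin = 5,
                           burnin_size = 100, seed = 8)
  pop <- simulate_population(cfg)
  founders <- pop$pedigree$generation == 0
  expect_equal(var(pop$tbv[founders, 1]), 1, tolerance = 1e-8)
  q <- pop$qtl[[1]]
  contrib <- apply(pop$qtl_genotypes[founders, , drop = FALSE], 2, var) *
    q$effect^2
  # the major QTL's marginal variance share is near the requested fraction
  expect_gt(max(contrib) / sum(contrib), 0.2)
})

test_that("degenerate configs are rejected", {
  expect_error(simulation_config(n_founders = 0), "degenerate")
  expect_error(simulation_config(h2 = 1.5), "h2")
  expect_error(simulation_config(n_qtl = 1e6), "n_qtl")
  expect_error(simulation_config(major_gene_fraction = 1), "major_gene")
  expect_error(simulation_config(n_generations = 3, split_generation = 3),
               "split")
})

test_that("adjacent-SNP LD decreases with founder population size", {
  mean_r2 <- function(n_b, seed) {
    cfg <- simulation_config(n_founders = 150, n_generations = 1,
                             n_chromosomes = 1, chrom_length_bp = 5e7,
                             snp_per_chrom = 80, n_qtl = 5, h2 = 0.5,
                             n_burnin = 30, burnin_size = n_b, seed = seed)
    M <- simulate_population(cfg)$genotypes$codes
    r <- vapply(seq_len(ncol(M) - 1), function(j)
      suppressWarnings(cor(M[, j], M[, j + 1]))^2, numeric(1))
    mean(r, na.rm = TRUE)
  }
  diffs <- vapply(1:6, function(s) mean_r2(25, s) - mean_r2(250, s),
                  numeric(1))
  # smaller bottleneck -> more drift -> more LD, in most replicates
  expect_gt(sum(diffs > 0), 4)
})

test_that("reliability formula matches its closed form and drives noise", {
  # hand evaluation: n = 100, h2 = 0.25 -> r2 = 6.25 / 7.1875
  r2 <- (100 * 0.25 / 4) / (1 + 99 * 0.25 / 4)
  expect_equal(r2, 6.25 / 7.1875, tolerance = 1e-12)
  expect_equal(r2, 0.8695652, tolerance = 1e-7)
  pop <- small_population(seed = 21, h2 = 0.25)
  n_animals <- nrow(pop$pedigree)
  ph <- simulate_phenotypes(pop, "t1", record_counts = rep(100, n_animals),
                            seed = 1)
  emp_var <- var(ph$value - pop$tbv[, 1])
  expect_equal(emp_var, 1 * (1 - r2) / r2, tolerance = 0.25)
})

test_that("phenotypes converge to TBV as records grow, and are noise at h2=0", {
  pop <- small_population(seed = 31, h2 = 0.25)
  n_animals <- nrow(pop$pedigree)
  ph <- simulate_phenotypes(pop, "t1", record_counts = rep(1e6, n_animals),
                            seed = 2)
  expect_gt(cor(ph$value, pop$tbv[, 1]), 0.99)
  # monotone in record count
  cors <- vapply(c(2, 20, 200), function(nrec) {
    mean(vapply(1:5, function(s) {
      p <- simulate_phenotypes(pop, "t1",
                               record_counts = rep(nrec, n_animals),
                               seed = s)
      cor(p$value, pop$tbv[, 1])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  # h2 = 0 pathway requires the explicit pure-noise flag
  expect_error(simulate_phenotypes(pop, "t1", h2 = 0), "pure_noise")
  pn <- simulate_phenotypes(pop, "t1", pure_noise = TRUE, seed = 3)
  expect_lt(abs(cor(pn$value, pop$tbv[, 1])),
            2.5 / sqrt(n_animals))
})

test_that("training/validation split follows generations and reports sire share", {
  pop <- small_population(seed = 41)
  sp <- split_sets(pop)
  ped <- pop$pedigree
  expect_setequal(sp$training_ids,
                  ped$animal[ped$generation < pop$config$split_generation])
  expect_length(intersect(sp$training_ids, sp$validation_ids), 0)
  expect_equal(sp$sire_in_training_fraction, 1)
  expect_error(split_sets(pop, split_generation = 0), "training")
  expect_error(split_sets(pop, split_generation = 99), "validation")
})

test_that("unknown-sire recording produces a no-sire validation group", {
  pop <- small_population(seed = 43, unknown_sire_rate = 0.2)
  sp <- split_sets(pop)
  expect_lt(sp$sire_in_training_fraction, 1)
  g <- group_by_sire(sp$validation_ids, sp$training_ids, pop$pedigree)
  expect_gt(length(g$no_sire), 0)
  expect_identical(check_mendelian(pop), 0L)  # genotypes still consistent
})

test_that("index traits are deterministic combinations of components", {
  traits <- standard_traits()
  cfg <- simulation_config(n_founders = 80, n_generations = 2,
                           n_chromosomes = 1, snp_per_chrom = 50,
                           n_qtl = 10, h2 = 0.4, n_burnin = 5,
                           burnin_size = 40, seed = 17)
  pop <- simulate_population(cfg, traits = traits)
  w <- index_weights$asi
  manual <- pop$tbv[, "protein"] * w["protein"] + pop$tbv[, "fat"] * w["fat"] +
    pop$tbv[, "milk"] * w["milk"]
  expect_equal(unname(pop$tbv[, "asi"]), unname(manual))
  # APR includes the survival index as a component
  expect_equal(unname(pop$tbv[, "apr"]),
               unname(as.numeric(
                 pop$tbv[, names(index_weights$apr)] %*% index_weights$apr)))
})
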