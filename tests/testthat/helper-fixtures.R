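# Fixture builders shared across the test files. Everything is generated
# in code under fixed seeds; nothing is stored on disk.

# random genotype matrix with a single-chromosome map
random_genotypes <- function(n, p, seed = 1, chrom_length = NULL,
                             n_chrom = 1) {
  set.seed(seed)
  codes <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  per <- ceiling(p / n_chrom)
  chrom <- rep(seq_len(n_chrom), each = per)[seq_len(p)]
  len <- chrom_length %||% 1e6
  map <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    k <- sum(chrom == ch)
    data.frame(snp_id = sprintf("s%d_%d", ch, seq_len(k)), chrom = ch,
               pos = sort(sample.int(len, k)))
  }))
  genotype_matrix(codes, sprintf("a%03d", seq_len(n)), map$snp_id, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent dense oracle for the ridge mixed model equations
dense_mme_solve <- function(X, y, lambda, w = rep(1, nrow(X))) {
  C <- rbind(c(sum(w), colSums(w * X)),
             cbind(colSums(w * X),
                   crossprod(X, w * X) + diag(lambda, ncol(X))))
  solve(C, c(sum(w * y), crossprod(X, w * y)))
}

# tiny population for fast end-to-end tests
small_population <- function(seed = 7, h2 = 0.5, n_generations = 3,
                             sigma2_g = 1, ...) {
  cfg <- simulation_config(
    n_founders = 120, n_generations = n_generations, n_sires_per_gen = 10,
    n_offspring_per_dam = 2, n_chromosomes = 2, chrom_length_bp = 5e7,
    snp_per_chrom = 60, n_qtl = 20, sigma2_g = sigma2_g, h2 = h2,
    n_burnin = 20, burnin_size = 60, seed = seed, ...)
  simulate_population(cfg)
}

# toy pedigree: unrelated founders A, B; offspring C, D (full sibs);
# E = offspring of half-sib mating via common sire A
toy_pedigree <- function() {
  data.frame(
    animal = c("A", "B", "M1", "M2", "C", "D", "X", "Y", "E"),
    sire = c(NA, NA, NA, NA, "A", "A", "A", "A", "X"),
    dam  = c(NA, NA, NA, NA, "B", "B", "M1", "M2", "Y"),
    birth_year = c(2000, 2000, 2000, 2000, 2001, 2001, 2001, 2001, 2002))
}

# gene-dropping oracle for the A matrix: expected allele sharing over
# many independent drops of two founder alleles per founder
gene_drop_a <- function(ped, n_drops = 10000, seed = 99) {
  set.seed(seed)
  ids <- ped$animal
  n <- length(ids)
  acc <- matrix(0, n, n, dimnames = list(ids, ids))
  for (rep in seq_len(n_drops)) {
    al <- matrix(NA_integer_, n, 2)
    next_allele <- 1L
    for (i in seq_len(n)) {
      s <- match(ped$sire[i], ids)
      d <- match(ped$dam[i], ids)
      a1 <- if (is.na(s)) { next_allele <- next_allele + 1L; next_allele }
            else al[s, sample.int(2, 1)]
      a2 <- if (is.na(d)) { next_allele <- next_allele + 1L; next_allele }
            else al[d, sample.int(2, 1)]
      al[i, ] <- c(a1, a2)
    }
    # kinship = mean IBD indicator over the four allele pairings;
    # numerator relationship a_ij = 2 * kinship
    share <- (outer(al[, 1], al[, 1], "==") + outer(al[, 1], al[, 2], "==") +
              outer(al[, 2], al[, 1], "==") + outer(al[, 2], al[, 2], "==")) / 4
    acc <- acc + 2 * share
  }
  acc / n_drops
}
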