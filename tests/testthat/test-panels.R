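# Subset construction: MAF, genome segments, the four strategies, overlap.

test_that("minor allele frequency follows the hand count and its symmetry", {
  g <- genotype_matrix(matrix(c(0, 1, 2, 2,  0, 0, 0, 0), 4, 2),
                       sprintf("a%d", 1:4), c("s1", "s2"),
                       data.frame(snp_id = c("s1", "s2"), chrom = 1,
                                  pos = c(100, 200)))
  maf <- compute_maf(g)
  expect_equal(maf$freq[1], 5 / 8)
  expect_equal(maf$maf[1], 0.375)
  expect_equal(maf$maf[2], 0)  # monomorphic
  # code flip 0 <-> 2 leaves MAF unchanged
  gf <- g
  gf$codes <- 2L - g$codes
  expect_equal(compute_maf(gf)$maf, maf$maf)
})

test_that("segments tile the cumulative genome and assign every SNP once", {
  map <- data.frame(snp_id = c("a", "b", "c", "d"), chrom = c(1, 1, 2, 2),
                    pos = c(1e6, 5e6, 1e6, 3e6))
  segs <- suppressWarnings(
    make_segments(map, 5, chrom_lengths = c("1" = 6e6, "2" = 4e6)))
  expect_equal(segs$total_length, 1e7)
  expect_equal(segs$boundaries$end - segs$boundaries$start, rep(2e6, 5))
  expect_equal(segs$boundaries$start, seq(0, 8e6, 2e6))
  # chromosome junction (cumulative 6e6) falls inside segment 4 (6e6, 8e6)
  expect_true(all(segs$snp_segment %in% 1:5))
  # SNP c at cumulative 6e6 + 1e6 - 1 -> segment 4
  expect_equal(segs$snp_segment[3], 4L)
  one <- make_segments(map, 1, chrom_lengths = c("1" = 6e6, "2" = 4e6))
  expect_equal(one$boundaries$end, 1e7)
  expect_warning(make_segments(map, 10), "empty")
  # 10-Mb chromosome split in two
  m2 <- data.frame(snp_id = c("x", "y"), chrom = 1, pos = c(2e6, 9e6))
  s2 <- make_segments(m2, 2, chrom_lengths = c("1" = 1e7))
  expect_equal(s2$boundaries$start, c(0, 5e6))
  expect_equal(s2$snp_segment, c(1L, 2L))
})

test_that("top selection is a prefix of the ranking", {
  g <- random_genotypes(40, 10, seed = 30)
  set.seed(30)
  y <- rnorm(40)
  rk <- backward_eliminate(g, y, "rr",
                           make_schedule(10,
                             breakpoints = data.frame(threshold = 5, step = 5),
                             first_drop = NULL, floor_size = 5),
                           hyperparameter = 4)
  expect_identical(select_top(rk, 10)$snp_ids, rk$entries$snp_id)
  expect_identical(select_top(rk, 1)$snp_ids, rk$entries$snp_id[1])
  expect_error(select_top(rk, 11), "exceeds")
})

test_that("even selection picks the best-ranked SNP per segment", {
  map <- data.frame(snp_id = c("s1", "s2", "s3", "s4"), chrom = 1,
                    pos = c(1e6, 4e6, 6e6, 9e6))
  segs <- make_segments(map, 2, chrom_lengths = c("1" = 1e7))
  rk <- structure(list(trait = "asi", method = "rr",
                       entries = data.frame(rank = 1:4,
                                            snp_id = c("s2", "s4", "s1", "s3"),
                                            elimination_step = NA,
                                            abs_coef = 4:1)),
                  class = "ranked_list")
  spec <- select_even(rk, segs, map)
  expect_setequal(spec$snp_ids, c("s2", "s4"))
  expect_equal(spec$n_actual, 2L)
  # MAF criterion with a tie: lower cumulative coordinate wins
  maf <- data.frame(snp_id = map$snp_id, freq = c(0.3, 0.3, 0.2, 0.2),
                    maf = c(0.3, 0.3, 0.2, 0.2))
  spec2 <- select_even(maf, segs, map)
  expect_setequal(spec2$snp_ids, c("s1", "s3"))
})

test_that("empty segments report a shortfall unless backfilled", {
  map <- data.frame(snp_id = c("s1", "s2"), chrom = 1, pos = c(1e5, 2e5))
  segs <- suppressWarnings(make_segments(map, 4,
                                         chrom_lengths = c("1" = 1e6)))
  maf <- data.frame(snp_id = map$snp_id, maf = c(0.1, 0.4))
  spec <- select_even(maf, segs, map)
  expect_equal(spec$n_actual, 1L)   # both SNP share segment 1
  expect_equal(spec$n_empty_segments, 3L)
  spec_bf <- select_even(maf, segs, map, backfill = TRUE)
  expect_equal(spec_bf$n_actual, 2L)
})

test_that("overlap percentages match enumeration and are anti-monotone in k", {
  mk <- function(ids) ldpanel:::new_subset_spec("trait_top", 2L, ids, "test")
  subs <- list(t1 = mk(c("1", "2")), t2 = mk(c("2", "3")),
               t3 = mk(c("2", "4")))
  ov <- overlap_analysis(subs)
  expect_true(all(ov$combinations$overlap_percent[ov$combinations$k == 2] ==
                    50))
  expect_equal(ov$combinations$overlap_percent[ov$combinations$k == 3], 50)
  expect_equal(ov$by_k$mean_overlap_percent, c(50, 50))
  # identical subsets -> 100 everywhere; disjoint -> 0
  same <- list(a = mk(c("1", "2")), b = mk(c("1", "2")), c = mk(c("1", "2")))
  expect_true(all(overlap_analysis(same)$combinations$overlap_percent == 100))
  disj <- list(a = mk(c("1", "2")), b = mk(c("3", "4")), c = mk(c("5", "6")))
  expect_true(all(overlap_analysis(disj)$combinations$overlap_percent == 0))
  expect_error(overlap_analysis(list(a = mk(c("1", "2")),
                                     b = ldpanel:::new_subset_spec(
                                       "trait_top", 3L, c("1", "2", "3"),
                                       "test"))),
               "n_requested")
  # anti-monotone: intersection of k+1 subsets is within any k of them
  set.seed(31)
  rand <- lapply(1:4, function(i)
    mk2 <- ldpanel:::new_subset_spec("trait_top", 10L,
                                     as.character(sample(30, 10)), "t"))
  names(rand) <- paste0("t", 1:4)
  ov2 <- overlap_analysis(rand)
  for (k in 3:4) {
    for (i in which(ov2$combinations$k == k)) {
      combo <- strsplit(ov2$combinations$traits[i], "+", fixed = TRUE)[[1]]
      subs_k <- utils::combn(combo, k - 1, simplify = FALSE)
      for (sk in subs_k) {
        parent <- ov2$combinations$overlap_percent[
          ov2$combinations$traits == paste(sk, collapse = "+")]
        expect_lte(ov2$combinations$overlap_percent[i], parent)
      }
    }
  }
})
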