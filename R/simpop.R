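# Forward-in-time simulator of pedigreed populations.
#
# Linkage disequilibrium is created by drift: founder haplotypes start in
# linkage equilibrium and are passed through a finite random-mating
# bottleneck population for a number of burn-in generations before the
# recorded pedigree begins. Recombination follows Haldane's map function at
# 1 cM/Mb.

#' Simulation configuration
#'
#' @param n_founders number of recorded founder animals (generation 0).
#' @param n_generations total number of discrete generations including the
#'   founders (generation indices `0 .. n_generations - 1`).
#' @param n_sires_per_gen number of males used as sires each generation.
#' @param n_offspring_per_dam offspring per dam per generation.
#' @param n_chromosomes,chrom_length_bp,snp_per_chrom genome layout; SNP
#'   positions are drawn uniformly per chromosome.
#' @param n_qtl number of causal loci (QTL). One pool of `n_qtl` loci is
#'   sampled from the simulated loci and shared by all direct traits, each
#'   trait drawing its own independent effects on the pool.
#' @param qtl_in_panel if `FALSE` (default), QTL loci are excluded from the
#'   returned genotyping panel, so markers predict through linkage
#'   disequilibrium only — emulating SNP-chip data where causal variants
#'   are untyped. The marker panel then has
#'   `n_chromosomes * snp_per_chrom - n_qtl` SNP. `TRUE` keeps QTL typed.
#' @param sigma2_g additive-genetic variance per trait; `0` gives a null
#'   architecture (all effects zero).
#' @param h2 narrow-sense heritability in `[0, 1]`.
#' @param major_gene_fraction fraction of `sigma2_g` assigned to a single
#'   QTL (in `[0, 1)`; `0` disables). Mirrors a DGAT1-like major gene; the
#'   remaining variance is split equally across the other QTL.
#' @param record_count_range integer range (min, max) of per-animal record
#'   counts (daughters/lactations) used for phenotype reliability.
#' @param split_generation first generation assigned to the validation set
#'   (`0 < split_generation < n_generations`).
#' @param unknown_sire_rate fraction of non-founder animals whose sire is
#'   left unrecorded in the pedigree (the genotype is still inherited from
#'   the true sire) — emulates incomplete pedigree recording, so that
#'   validation sets contain animals without a sire in training.
#' @param founder_maf range of the uniform allele-frequency distribution for
#'   burn-in founder haplotypes.
#' @param n_burnin number of pre-pedigree random-mating generations.
#' @param burnin_size diploid size of the bottleneck population that
#'   accumulates LD during burn-in.
#' @param cm_per_mb genetic map density (centimorgans per megabase).
#' @param base_year birth year of the founder generation; each later
#'   generation is born one year later.
#' @param seed master integer seed; all stages derive named sub-streams.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_founders = 200, n_generations = 3,
                              n_sires_per_gen = 20, n_offspring_per_dam = 2,
                              n_chromosomes = 5, chrom_length_bp = 1e8,
                              snp_per_chrom = 200, n_qtl = 50,
                              qtl_in_panel = FALSE,
                              sigma2_g = 1, h2 = 0.3,
                              major_gene_fraction = 0,
                              record_count_range = c(30L, 150L),
                              split_generation = n_generations - 1L,
                              unknown_sire_rate = 0,
                              founder_maf = c(0.05, 0.5),
                              n_burnin = 50, burnin_size = 100,
                              cm_per_mb = 1, base_year = 1990, seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              n_sires_per_gen = as.integer(n_sires_per_gen),
              n_offspring_per_dam = as.integer(n_offspring_per_dam),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              snp_per_chrom = as.integer(snp_per_chrom),
              n_qtl = as.integer(n_qtl),
              qtl_in_panel = isTRUE(qtl_in_panel),
              sigma2_g = as.numeric(sigma2_g),
              h2 = as.numeric(h2),
              major_gene_fraction = as.numeric(major_gene_fraction),
              record_count_range = as.integer(record_count_range),
              split_generation = as.integer(split_generation),
              unknown_sire_rate = as.numeric(unknown_sire_rate),
              founder_maf = as.numeric(founder_maf),
              n_burnin = as.integer(n_burnin),
              burnin_size = as.integer(burnin_size),
              cm_per_mb = as.numeric(cm_per_mb),
              base_year = as.integer(base_year), seed = as.integer(seed))
  p_total <- cfg$n_chromosomes * cfg$snp_per_chrom
  if (cfg$n_founders < 2 || p_total < 1)
    stop_ld("degenerate config: need >= 2 founders and >= 1 SNP")
  if (cfg$h2 < 0 || cfg$h2 > 1) stop_ld("h2 must lie in [0, 1]")
  if (cfg$n_qtl > p_total)
    stop_ld("n_qtl (%d) exceeds total SNP (%d)", cfg$n_qtl, p_total)
  if (!cfg$qtl_in_panel && cfg$n_qtl >= p_total)
    stop_ld("no markers left after excluding %d QTL from %d loci",
            cfg$n_qtl, p_total)
  if (cfg$major_gene_fraction < 0 || cfg$major_gene_fraction >= 1)
    stop_ld("major_gene_fraction must lie in [0, 1)")
  if (cfg$unknown_sire_rate < 0 || cfg$unknown_sire_rate >= 1)
    stop_ld("unknown_sire_rate must lie in [0, 1)")
  if (cfg$n_generations < 1) stop_ld("need at least one generation")
  if (cfg$n_generations > 1 &&
      (cfg$split_generation < 1 || cfg$split_generation >= cfg$n_generations))
    stop_ld("split_generation must satisfy 0 < split < n_generations")
  class(cfg) <- "simulation_config"
  cfg
}

# Recombination fraction between adjacent loci (Haldane), plus a free 0.5
# at the first locus of the genome and at chromosome starts.
recomb_fractions <- function(map, cm_per_mb) {
  p <- nrow(map)
  r <- numeric(p)
  r[1] <- 0.5
  if (p > 1) {
    same <- map$chrom[-1] == map$chrom[-p]
    d_morgan <- (map$pos[-1] - map$pos[-p]) * cm_per_mb * 1e-8
    r[-1] <- ifelse(same, 0.5 * (1 - exp(-2 * d_morgan)), 0.5)
  }
  r
}

# Draw one gamete per entry of parent_idx from a haplotype pool
# (2 rows per diploid individual). rfrac[1] must be 0.5 (random phase).
make_gametes <- function(pool, parent_idx, rfrac) {
  G <- length(parent_idx)
  p <- ncol(pool)
  cross <- matrix(stats::runif(G * p) < rep(rfrac, each = G), G, p)
  m <- cross
  if (p > 1) for (j in 2:p) m[, j] <- xor(m[, j - 1L], cross[, j])
  ha <- pool[2L * parent_idx - 1L, , drop = FALSE]
  hb <- pool[2L * parent_idx, , drop = FALSE]
  ha[m] <- hb[m]
  ha
}

# One generation of random mating inside the burn-in bottleneck.
burnin_generation <- function(pool, n_ind, rfrac) {
  pa <- sample.int(n_ind, n_ind, replace = TRUE)
  pb <- (pa + sample.int(n_ind - 1L, n_ind, replace = TRUE) - 1L) %% n_ind + 1L
  g1 <- make_gametes(pool, pa, rfrac)
  g2 <- make_gametes(pool, pb, rfrac)
  out <- matrix(0L, 2L * n_ind, ncol(pool))
  out[seq(1L, 2L * n_ind, by = 2L), ] <- g1
  out[seq(2L, 2L * n_ind, by = 2L), ] <- g2
  out
}

#' Simulate a pedigreed population
#'
#' Generates a SNP map, burns in LD through a finite bottleneck population,
#' founds a recorded pedigree from the burn-in gene pool, and gene-drops
#' haplotypes through `n_generations` of discrete random mating with
#' `n_sires_per_gen` sires per generation. True breeding values (TBV) are
#' sums of QTL dosages times effects, rescaled so that the founder-generation
#' TBV variance equals `sigma2_g` per direct trait; index-trait TBV are the
#' weighted sums of their components.
#'
#' @param config a `simulation_config`.
#' @param traits optional named list of `trait_definition`s; by default a
#'   single direct trait `"t1"` with the config's `h2`.
#' @return A `population` object: `pedigree` (data.frame of animal, sire,
#'   dam, sex, generation, birth_year), `genotypes` (a `genotype_matrix` of
#'   the marker panel), `tbv` (animals x traits matrix), `qtl` (per direct
#'   trait: causal locus ids and effects), `qtl_genotypes` (animals x QTL
#'   dosages of the shared causal pool), `traits`, `config`.
#' @export
simulate_population <- function(config, traits = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(traits))
    traits <- stats::setNames(list(trait_definition("t1", h2 = config$h2)), "t1")
  direct <- traits[vapply(traits, function(t) t$kind == "direct", TRUE)]
  p <- config$n_chromosomes * config$snp_per_chrom

  # genome map: uniform SNP positions per chromosome
  map <- with_seed(substream_seed(config$seed, "map"), {
    do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ch) {
      pos <- sort(sample.int(config$chrom_length_bp, config$snp_per_chrom))
      data.frame(snp_id = sprintf("snp_%d_%d", ch, seq_along(pos)),
                 chrom = ch, pos = pos)
    }))
  })
  rfrac <- recomb_fractions(map, config$cm_per_mb)

  # burn-in: drift in a finite bottleneck creates LD
  pool <- with_seed(substream_seed(config$seed, "haplotypes"), {
    f <- stats::runif(p, config$founder_maf[1], config$founder_maf[2])
    n_b <- config$burnin_size
    pool <- matrix(stats::runif(2L * n_b * p) < rep(f, each = 2L * n_b),
                   2L * n_b, p)
    for (g in seq_len(config$n_burnin))
      pool <- burnin_generation(pool, n_b, rfrac)
    pool
  })

  # pedigree + gene dropping
  sim <- with_seed(substream_seed(config$seed, "pedigree"), {
    n_b <- config$burnin_size
    ped <- list()
    hap <- list()  # per generation: 2*N x p
    # founders: two independent gametes from the burn-in pool
    nf <- config$n_founders
    pa <- sample.int(n_b, nf, replace = TRUE)
    pb <- (pa + sample.int(n_b - 1L, nf, replace = TRUE) - 1L) %% n_b + 1L
    g1 <- make_gametes(pool, pa, rfrac)
    g2 <- make_gametes(pool, pb, rfrac)
    H <- matrix(FALSE, 2L * nf, p)
    H[seq(1L, 2L * nf, 2L), ] <- g1
    H[seq(2L, 2L * nf, 2L), ] <- g2
    sex <- rep_len(c("M", "F"), nf)[sample.int(nf)]
    ped[[1]] <- data.frame(animal = sprintf("G0_%04d", seq_len(nf)),
                           sire = NA_character_, dam = NA_character_,
                           sex = sex, generation = 0L,
                           birth_year = config$base_year)
    hap[[1]] <- H
    for (g in seq_len(config$n_generations - 1L)) {
      prev <- ped[[g]]
      males <- which(prev$sex == "M")
      females <- which(prev$sex == "F")
      if (!length(males) || !length(females))
        stop_ld("generation %d has no %s", g - 1L,
                if (!length(males)) "males" else "females")
      n_s <- min(config$n_sires_per_gen, length(males))
      sires <- males[sample.int(length(males), n_s)]
      dam_idx <- rep(females, each = config$n_offspring_per_dam)
      sire_idx <- sires[sample.int(length(sires), length(dam_idx),
                                   replace = TRUE)]
      n_off <- length(dam_idx)
      gs <- make_gametes(hap[[g]], sire_idx, rfrac)
      gd <- make_gametes(hap[[g]], dam_idx, rfrac)
      Hg <- matrix(FALSE, 2L * n_off, p)
      Hg[seq(1L, 2L * n_off, 2L), ] <- gs
      Hg[seq(2L, 2L * n_off, 2L), ] <- gd
      sire_rec <- prev$animal[sire_idx]
      if (config$unknown_sire_rate > 0)
        sire_rec[stats::runif(n_off) < config$unknown_sire_rate] <-
          NA_character_
      ped[[g + 1L]] <- data.frame(
        animal = sprintf("G%d_%04d", g, seq_len(n_off)),
        sire = sire_rec, dam = prev$animal[dam_idx],
        sex = rep_len(c("M", "F"), n_off)[sample.int(n_off)],
        generation = g, birth_year = config$base_year + g)
      hap[[g + 1L]] <- Hg
    }
    pedigree <- do.call(rbind, ped)
    rownames(pedigree) <- NULL
    codes <- do.call(rbind, lapply(hap, function(H) {
      n <- nrow(H) / 2L
      H[seq(1L, nrow(H), 2L), , drop = FALSE] +
        H[seq(2L, nrow(H), 2L), , drop = FALSE]
    }))
    storage.mode(codes) <- "integer"
    list(pedigree = pedigree, codes = codes)
  })

  # one shared pool of causal loci; by default they are untyped (off the
  # marker panel), so markers predict through LD only
  founder_rows <- which(sim$pedigree$generation == 0L)
  qtl_idx <- with_seed(substream_seed(config$seed, "qtl"),
                       sort(sample.int(p, config$n_qtl)))
  qtl_codes <- sim$codes[, qtl_idx, drop = FALSE]
  marker_idx <- if (config$qtl_in_panel) seq_len(p)
                else setdiff(seq_len(p), qtl_idx)
  geno <- genotype_matrix(sim$codes[, marker_idx, drop = FALSE],
                          sim$pedigree$animal, map$snp_id[marker_idx],
                          map[marker_idx, , drop = FALSE])

  # per-trait effects on the pool, rescaled on the founder generation
  qtl_f <- qtl_codes[founder_rows, , drop = FALSE]
  qtl <- with_seed(substream_seed(config$seed, "effects"), {
    lapply(direct, function(tr) {
      if (config$sigma2_g == 0) {
        eff <- numeric(config$n_qtl)
      } else if (config$major_gene_fraction > 0 && config$n_qtl >= 1) {
        f <- config$major_gene_fraction
        major <- sample.int(config$n_qtl, 1L)
        eff <- numeric(config$n_qtl)
        vg <- apply(qtl_f, 2, stats::var)
        vg[vg == 0] <- NA
        eff[major] <- sqrt(f * config$sigma2_g / vg[major])
        rest <- setdiff(seq_len(config$n_qtl), major)
        if (length(rest)) {
          per <- (1 - f) * config$sigma2_g / length(rest)
          eff[rest] <- sample(c(-1, 1), length(rest), replace = TRUE) *
            sqrt(per / vg[rest])
        }
        eff[is.na(eff)] <- 0
        # common rescale to hit sigma2_g exactly in the founders
        s <- stats::var(as.numeric(qtl_f %*% eff))
        if (s > 0) eff <- eff * sqrt(config$sigma2_g / s)
      } else {
        eff <- stats::rnorm(config$n_qtl)
        s <- stats::var(as.numeric(qtl_f %*% eff))
        if (s > 0) eff <- eff * sqrt(config$sigma2_g / s) else eff[] <- 0
      }
      list(snp_index = qtl_idx, snp_id = map$snp_id[qtl_idx], effect = eff)
    })
  })

  tbv <- matrix(0, nrow(sim$pedigree), length(traits),
                dimnames = list(sim$pedigree$animal, names(traits)))
  for (nm in names(direct))
    tbv[, nm] <- as.numeric(qtl_codes %*% qtl[[nm]]$effect)
  for (nm in names(traits)) {
    tr <- traits[[nm]]
    if (tr$kind == "index") {
      comps <- lapply(names(tr$index_weights), function(cn) {
        if (!cn %in% colnames(tbv))
          stop_ld("index '%s': component trait '%s' not simulated", nm, cn)
        tbv[, cn]
      })
      names(comps) <- names(tr$index_weights)
      tbv[, nm] <- compute_index(comps, tr)
    }
  }

  structure(list(pedigree = sim$pedigree, genotypes = geno, tbv = tbv,
                 qtl = qtl, qtl_genotypes = qtl_codes, traits = traits,
                 config = config),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf(
    "population: %d animals, %d generations, %d SNP, %d trait(s)\n",
    nrow(x$pedigree), x$config$n_generations, ncol(x$genotypes$codes),
    ncol(x$tbv)))
  invisible(x)
}

#' Check Mendelian consistency of simulated genotypes
#'
#' For every offspring-parent pair, an offspring dosage is consistent iff it
#' lies between the minimum and maximum dosage transmissible by its parents
#' (a parent coded 0 can only transmit the reference allele, a parent coded
#' 2 only the alternative, a heterozygote either).
#'
#' @param population a `population`.
#' @return Number of (animal, locus) Mendelian violations (0 for any
#'   gene-dropped population).
#' @export
check_mendelian <- function(population) {
  ped <- population$pedigree
  codes <- population$genotypes$codes
  non_founders <- which(!is.na(ped$sire) & !is.na(ped$dam))
  if (!length(non_founders)) return(0L)
  gs <- codes[match(ped$sire[non_founders], ped$animal), , drop = FALSE]
  gd <- codes[match(ped$dam[non_founders], ped$animal), , drop = FALSE]
  go <- codes[non_founders, , drop = FALSE]
  lo <- (gs == 2L) + (gd == 2L)
  hi <- (gs > 0L) + (gd > 0L)
  sum(go < lo | go > hi)
}

#' Simulate record-count-dependent phenotypes
#'
#' Emulates deregressed proofs: the phenotype is the true breeding value
#' plus noise whose variance shrinks with the phenotype's reliability,
#' `y_i = TBV_i + e_i`, `e_i ~ N(0, sigma2_g (1 - r2_i) / r2_i)`. The
#' reliability follows the progeny-test approximation
#' `r2_i = (n_i h2 / 4) / (1 + (n_i - 1) h2 / 4)` from the record count
#' `n_i`.
#'
#' @param population a `population` with TBV for `trait`.
#' @param trait trait name (a column of `population$tbv`), or a
#'   `trait_definition`.
#' @param record_counts per-animal record counts aligned with the pedigree;
#'   `NULL` draws them uniformly from the config's `record_count_range`.
#' @param seed integer seed for the noise stream; `NULL` derives one from
#'   the config seed and the trait name.
#' @param pure_noise if `TRUE`, the phenotype is pure noise unrelated to the
#'   TBV (the only valid pathway at `h2 = 0`).
#' @param h2 heritability used in the reliability formula; defaults to the
#'   trait's own `h2` (or the config's for the default trait).
#' @param reliability_fn optional override: `function(n, h2) -> r2` in
#'   `(0, 1]`, replacing the progeny-test approximation.
#' @return A data.frame (`animal_id`, `trait`, `value`, `record_count`,
#'   `birth_year`) — one row per animal.
#' @export
simulate_phenotypes <- function(population, trait, record_counts = NULL,
                                seed = NULL, pure_noise = FALSE, h2 = NULL,
                                reliability_fn = NULL) {
  trait_name <- if (inherits(trait, "trait_definition")) trait$name else trait
  if (!trait_name %in% colnames(population$tbv))
    stop_ld("no TBV for trait '%s'", trait_name)
  cfg <- population$config
  if (is.null(h2)) {
    tr <- population$traits[[trait_name]]
    h2 <- if (!is.null(tr) && is.finite(tr$h2)) tr$h2 else cfg$h2
  }
  if (is.null(seed))
    seed <- substream_seed(cfg$seed, paste0("noise:", trait_name))
  n_animals <- nrow(population$pedigree)
  if (is.null(record_counts)) {
    rng <- cfg$record_count_range
    record_counts <- with_seed(substream_seed(cfg$seed,
                                              paste0("records:", trait_name)),
      sample(seq(rng[1], rng[2]), n_animals, replace = TRUE))
  }
  if (length(record_counts) != n_animals)
    stop_ld("record_counts length (%d) != animals (%d)",
            length(record_counts), n_animals)
  if (any(record_counts < 1)) stop_ld("record_count must be >= 1")
  tbv <- population$tbv[, trait_name]
  value <- with_seed(seed, {
    if (pure_noise) {
      sd0 <- if (cfg$sigma2_g > 0) sqrt(cfg$sigma2_g) else 1
      stats::rnorm(n_animals, 0, sd0)
    } else {
      if (h2 <= 0)
        stop_ld(paste("h2 = 0 gives zero reliability; use pure_noise = TRUE",
                      "to simulate an uninformative phenotype"))
      r2 <- if (is.null(reliability_fn)) {
        (record_counts * h2 / 4) / (1 + (record_counts - 1) * h2 / 4)
      } else reliability_fn(record_counts, h2)
      if (any(r2 <= 0 | r2 > 1)) stop_ld("reliability outside (0, 1]")
      noise_var <- cfg$sigma2_g * (1 - r2) / r2
      tbv + stats::rnorm(n_animals, 0, sqrt(noise_var))
    }
  })
  data.frame(animal_id = population$pedigree$animal, trait = trait_name,
             value = value, record_count = as.integer(record_counts),
             birth_year = population$pedigree$birth_year)
}

#' Split a population into training and validation sets
#'
#' Animals born in generations before `split_generation` (equivalently,
#' before the matching birth-year threshold) form the training set; later
#' generations form the validation set — emulating the progeny-test design
#' where proven bulls train the model and young animals are validated.
#'
#' @param population a `population`.
#' @param split_generation first validation generation; defaults to the
#'   config's `split_generation`.
#' @return List: `training_ids`, `validation_ids`, and
#'   `sire_in_training_fraction` (share of validation animals whose sire is
#'   a training animal).
#' @export
split_sets <- function(population, split_generation = NULL) {
  ped <- population$pedigree
  sg <- split_generation %||% population$config$split_generation
  training_ids <- ped$animal[ped$generation < sg]
  validation_ids <- ped$animal[ped$generation >= sg]
  if (!length(training_ids)) stop_ld("empty training set (split too early)")
  if (!length(validation_ids)) stop_ld("empty validation set (split too late)")
  sires <- ped$sire[match(validation_ids, ped$animal)]
  frac <- mean(!is.na(sires) & sires %in% training_ids)
  list(training_ids = training_ids, validation_ids = validation_ids,
       sire_in_training_fraction = frac)
}
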