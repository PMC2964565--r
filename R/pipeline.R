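# Config-driven orchestration: simulate -> fit -> rank -> select -> refit
# per subset -> predict -> evaluate, with every artifact written to a run
# directory together with a manifest (config hash, seed, package version).

#' Pipeline run configuration
#'
#' @param simulation a `simulation_config` (exactly one of `simulation` /
#'   `input_paths` must be given).
#' @param input_paths named list of existing input files (`genotypes`,
#'   `map`, `phenotypes`, `pedigree`, plus `training_ids`/`validation_ids`
#'   files with one id per line).
#' @param traits trait names to analyse (components needed by requested
#'   index traits are simulated automatically).
#' @param methods prediction engines to run (`"rr"`, `"plsr"`).
#' @param subset_sizes low-density panel sizes to evaluate.
#' @param strategies subset construction strategies, among `"trait_top"`,
#'   `"even_asi"`, `"even_apr"`, `"even_maf"`.
#' @param schedule_breakpoints optional custom breakpoints data.frame for
#'   [make_schedule()]; `schedule_floor` the smallest ranked subset.
#' @param cv a `cv_config` used for all hyperparameter tuning.
#' @param fixed_hyperparameter optional named list (`rr` = lambda,
#'   `plsr` = n_components) disabling tuning (mainly for fast smoke runs).
#' @param out_dir run directory (created).
#' @param seed global integer seed.
#' @return A `run_config` object.
#' @export
run_config <- function(simulation = NULL, input_paths = NULL,
                       traits = c("asi", "apr"),
                       methods = c("rr", "plsr"),
                       subset_sizes = c(100, 300, 500, 1000, 3000, 5000),
                       strategies = c("trait_top", "even_asi", "even_apr",
                                      "even_maf"),
                       schedule_breakpoints = NULL, schedule_floor = 100,
                       cv = cv_config(), fixed_hyperparameter = NULL,
                       out_dir = tempfile("ldpanel_run_"), seed = 1L) {
  if (is.null(simulation) == is.null(input_paths))
    stop_ld("exactly one of 'simulation' or 'input_paths' must be given")
  methods <- match.arg(methods, c("rr", "plsr"), several.ok = TRUE)
  strategies <- match.arg(strategies,
                          c("trait_top", "even_asi", "even_apr", "even_maf"),
                          several.ok = TRUE)
  if (!is.null(simulation)) {
    p <- simulation$n_chromosomes * simulation$snp_per_chrom -
      (if (simulation$qtl_in_panel) 0L else simulation$n_qtl)
    if (any(subset_sizes > p))
      stop_ld("subset size(s) exceed the marker panel (%d SNP)", p)
  }
  structure(list(simulation = simulation, input_paths = input_paths,
                 traits = traits, methods = methods,
                 subset_sizes = as.integer(sort(subset_sizes)),
                 strategies = strategies,
                 schedule_breakpoints = schedule_breakpoints,
                 schedule_floor = as.integer(schedule_floor), cv = cv,
                 fixed_hyperparameter = fixed_hyperparameter,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Simulate phenotypes for a trait, resolving index components
#'
#' Direct traits get record-count-dependent noise via
#' [simulate_phenotypes()]; index traits are the weighted sum of their
#' components' phenotypes (components resolved recursively, so APR picks
#' up the survival index automatically).
#'
#' @param population a `population` whose `traits` include `trait_name`
#'   and any components.
#' @param trait_name trait to resolve.
#' @param record_counts shared per-animal record counts (`NULL`: one draw
#'   per population from the config range).
#' @return Phenotype data.frame as from [simulate_phenotypes()].
#' @export
trait_phenotypes <- function(population, trait_name, record_counts = NULL) {
  tr <- population$traits[[trait_name]]
  if (is.null(tr)) stop_ld("trait '%s' not defined in population", trait_name)
  if (is.null(record_counts)) {
    rng <- population$config$record_count_range
    record_counts <- with_seed(
      substream_seed(population$config$seed, "records"),
      sample(seq(rng[1], rng[2]), nrow(population$pedigree), replace = TRUE))
  }
  if (tr$kind == "direct")
    return(simulate_phenotypes(population, trait_name,
                               record_counts = record_counts))
  comps <- lapply(names(tr$index_weights), function(cn)
    trait_phenotypes(population, cn, record_counts)$value)
  names(comps) <- names(tr$index_weights)
  data.frame(animal_id = population$pedigree$animal, trait = trait_name,
             value = compute_index(comps, tr),
             record_count = as.integer(record_counts),
             birth_year = population$pedigree$birth_year)
}

fit_and_eval <- function(Xtr, ytr, Xval, yval_list, method, cv, fixed_hp,
                         weights = NULL) {
  hp <- fixed_hp[[method]]
  fit <- fit_engine(Xtr, ytr, method, cv, hyperparameter = hp, weights)
  dgv <- predict_dgv(Xval, fit$effects)
  list(fit = fit, dgv = dgv)
}

#' Run the full pipeline
#'
#' Executes: simulate (or load) -> split -> fit the full panel per trait
#' and method -> backward-eliminate to rank SNP -> construct subsets by
#' the requested strategies and sizes -> refit per subset (hyperparameter
#' re-tuned) -> predict validation DGV -> evaluate accuracy, relative
#' accuracy and sire-in-training groups. All artifacts and a manifest are
#' written under `config$out_dir`.
#'
#' @param config a `run_config`.
#' @param verbose log stage progress.
#' @return Invisibly, a list with `results` (evaluation rows), `summary`,
#'   `rankings`, `subsets`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("ldpanel")),
                   stages = list(), started = format(t0))
  write_manifest <- function(status = "running") {
    manifest$status <- status
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
  }
  stage <- function(name, expr) {
    ld_log("stage: %s", name, verbose = verbose)
    t1 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest("failed")
      stop_ld("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(as.numeric(Sys.time() - t1, "secs"), 2))
    write_manifest()
    out
  }

  # --- inputs -------------------------------------------------------------
  dat <- stage("simulate", {
    if (!is.null(config$simulation)) {
      simcfg <- config$simulation
      simcfg$seed <- substream_seed(config$seed, "simulation")
      pop <- simulate_population(simcfg, traits = standard_traits())
      split <- split_sets(pop)
      write_genotypes(pop$genotypes, file.path(config$out_dir,
                                               "genotypes.tsv"))
      write_pedigree(pop$pedigree, file.path(config$out_dir, "pedigree.csv"))
      phe <- do.call(rbind, lapply(config$traits, function(tn)
        trait_phenotypes(pop, tn)))
      write_phenotypes(phe, file.path(config$out_dir, "phenotypes.tsv"))
      list(geno = pop$genotypes, pedigree = pop$pedigree, phenotypes = phe,
           split = split, population = pop)
    } else {
      ip <- config$input_paths
      geno <- read_genotypes(ip$genotypes, ip$map %||%
                               paste0(ip$genotypes, ".map.tsv"))
      phe <- read_phenotypes(ip$phenotypes)
      ped <- read_pedigree(ip$pedigree)
      tr_ids <- readLines(ip$training_ids)
      va_ids <- readLines(ip$validation_ids)
      sires <- ped$sire[match(va_ids, ped$animal)]
      list(geno = geno, pedigree = ped, phenotypes = phe,
           split = list(training_ids = tr_ids, validation_ids = va_ids,
                        sire_in_training_fraction =
                          mean(!is.na(sires) & sires %in% tr_ids)),
           population = NULL)
    }
  })
  Xtr_full <- subset_genotypes(dat$geno, animals = dat$split$training_ids)
  Xval_full <- subset_genotypes(dat$geno, animals = dat$split$validation_ids)
  p_total <- length(dat$geno$snp_ids)
  groups <- c(list(all = dat$split$validation_ids),
              group_by_sire(dat$split$validation_ids, dat$split$training_ids,
                            dat$pedigree))

  pheno_of <- function(trait, ids) {
    rows <- dat$phenotypes[dat$phenotypes$trait == trait, ]
    stats::setNames(rows$value, rows$animal_id)[ids]
  }

  cvg <- config$cv
  cvg$fold_seed <- substream_seed(config$seed, "folds")
  fixed_hp <- config$fixed_hyperparameter %||% list()

  # --- full-panel fits ----------------------------------------------------
  full_fits <- stage("fit_full", {
    out <- list()
    for (tn in config$traits) {
      ytr <- pheno_of(tn, dat$split$training_ids)
      for (m in config$methods) {
        fe <- fit_and_eval(Xtr_full, ytr, Xval_full, NULL, m, cvg, fixed_hp)
        write_effects(fe$fit$effects,
                      file.path(config$out_dir,
                                sprintf("effects_full_%s_%s.tsv", tn, m)))
        out[[paste(tn, m, sep = ".")]] <- fe
      }
    }
    out
  })

  # --- ranking ------------------------------------------------------------
  need_rank <- unique(c(
    if ("trait_top" %in% config$strategies) config$traits,
    if ("even_asi" %in% config$strategies) "asi",
    if ("even_apr" %in% config$strategies) "apr"))
  schedule <- make_schedule(p_total,
                            breakpoints = config$schedule_breakpoints,
                            floor_size = config$schedule_floor)
  rankings <- stage("rank", {
    out <- list()
    for (tn in need_rank) {
      ytr <- pheno_of(tn, dat$split$training_ids)
      for (m in config$methods) {
        rk <- backward_eliminate(Xtr_full, ytr, m, schedule, cvg,
                                 hyperparameter = fixed_hp[[m]], trait = tn)
        write_ranked_list(rk, file.path(config$out_dir,
                                        sprintf("ranking_%s_%s.tsv", tn, m)))
        out[[paste(tn, m, sep = ".")]] <- rk
      }
    }
    out
  })

  # --- subset construction ------------------------------------------------
  subsets <- stage("select", {
    out <- list()
    maf <- if ("even_maf" %in% config$strategies) compute_maf(Xtr_full)
    for (n in config$subset_sizes) {
      segs <- if (any(grepl("^even", config$strategies)))
        make_segments(dat$geno$map, n)
      for (strat in config$strategies) {
        specs <- switch(strat,
          trait_top = {
            ss <- lapply(config$traits, function(tn) lapply(
              config$methods, function(m)
                select_top(rankings[[paste(tn, m, sep = ".")]], n)))
            stats::setNames(
              unlist(ss, recursive = FALSE),
              as.vector(t(outer(config$traits, config$methods, paste,
                                sep = "."))))
          },
          even_asi = ,
          even_apr = {
            tn <- sub("^even_", "", strat)
            stats::setNames(lapply(config$methods, function(m)
              select_even(rankings[[paste(tn, m, sep = ".")]], segs,
                          dat$geno$map)), config$methods)
          },
          even_maf = list(maf = select_even(maf, segs, dat$geno$map)))
        for (nm in names(specs)) {
          key <- sprintf("%s.%d.%s", strat, n, nm)
          write_subset(specs[[nm]],
                       file.path(config$out_dir,
                                 sprintf("subset_%s_%d_%s.tsv", strat, n, nm)))
          out[[key]] <- c(specs[[nm]], list(strategy_requested = strat,
                                            n = n, fit_key = nm))
        }
      }
    }
    out
  })

  # --- refit per subset, predict, evaluate --------------------------------
  results <- stage("evaluate", {
    rows <- list()
    add_row <- function(row) rows[[length(rows) + 1L]] <<- row
    full_acc <- list()
    for (tn in config$traits) {
      for (m in config$methods) {
        dgv <- full_fits[[paste(tn, m, sep = ".")]]$dgv
        for (g in names(groups)) {
          ids <- groups[[g]]
          acc <- if (length(ids) >= 2)
            suppressWarnings(accuracy(dgv[ids], pheno_of(tn, ids)))
          else NA_real_
          full_acc[[paste(tn, m, g, sep = ".")]] <- acc
          add_row(evaluation_result(tn, m, "full", p_total, g, dgv[ids],
                                    pheno_of(tn, ids), acc_full = acc))
        }
      }
    }
    for (key in names(subsets)) {
      sub <- subsets[[key]]
      strat <- sub$strategy_requested
      for (tn in config$traits) {
        # trait-specific subsets only evaluate their own trait
        if (strat == "trait_top" &&
            !startsWith(sub$fit_key, paste0(tn, "."))) next
        methods_here <- if (strat == "trait_top")
          sub("^.*\\.", "", sub$fit_key)
        else if (strat %in% c("even_asi", "even_apr")) sub$fit_key
        else config$methods
        for (m in intersect(methods_here, config$methods)) {
          Xtr <- subset_genotypes(Xtr_full, snps = sub$snp_ids)
          Xva <- subset_genotypes(Xval_full, snps = sub$snp_ids)
          ytr <- pheno_of(tn, dat$split$training_ids)
          fe <- fit_and_eval(Xtr, ytr, Xva, NULL, m, cvg, fixed_hp)
          for (g in names(groups)) {
            ids <- groups[[g]]
            if (length(ids) < 2) next
            add_row(evaluation_result(
              tn, m, strat, sub$n, g, fe$dgv[ids], pheno_of(tn, ids),
              acc_full = full_acc[[paste(tn, m, g, sep = ".")]]))
          }
        }
      }
    }
    res <- do.call(rbind, rows)
    utils::write.table(res, file.path(config$out_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  summary_tab <- stage("summarize", {
    st <- summarize_results(results)
    utils::write.table(st, file.path(config$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    A <- a_matrix(dat$pedigree)
    rs <- relationship_summary(A, dat$split$training_ids, groups)
    utils::write.table(rs, file.path(config$out_dir,
                                     "relationship_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    st
  })

  manifest$finished <- format(Sys.time())
  manifest$sire_in_training_fraction <- dat$split$sire_in_training_fraction
  manifest <- write_manifest("ok")
  invisible(list(results = results, summary = summary_tab,
                 rankings = rankings, subsets = subsets,
                 manifest = manifest, out_dir = config$out_dir))
}
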