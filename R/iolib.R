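# Readers and writers for all on-disk artifacts, with strict validation.
# Genotypes: tab-separated animals x SNP dosage matrix, or PLINK .raw
# dialect (whitespace-separated, header, 6 leading non-genotype columns).
# Maps are TSV (snp_id, chrom, pos); phenotypes TSV; pedigrees CSV.

#' Write / read a genotype matrix as TSV
#'
#' The TSV layout is animals x SNP: first column `animal_id`, one column
#' per SNP named by its id, dosage codes 0/1/2 (empty or `NA` for
#' missing). The map travels in a companion TSV.
#'
#' @param x a `genotype_matrix`.
#' @param path genotype TSV path.
#' @param map_path map TSV path; defaults to `<path>.map.tsv`.
#' @return `write_genotypes`: the paths, invisibly. `read_genotypes`: a
#'   `genotype_matrix`.
#' @export
write_genotypes <- function(x, path, map_path = paste0(path, ".map.tsv")) {
  stopifnot(inherits(x, "genotype_matrix"))
  df <- data.frame(animal_id = x$animal_ids, x$codes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_map(x$map, map_path)
  invisible(c(path, map_path))
}

#' @param dialect `"tsv"` (the layout above) or `"plink_raw"` (PLINK
#'   `--recode A` text: columns FID IID PAT MAT SEX PHENOTYPE then one
#'   dosage column per SNP named `<snp_id>_<allele>`).
#' @param impute_missing replace missing codes by the per-SNP rounded mean
#'   (the count imputed is reported via a message); otherwise missing
#'   codes are an error.
#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, map_path = paste0(path, ".map.tsv"),
                           dialect = c("tsv", "plink_raw"),
                           impute_missing = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_ld("no such file: %s", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    if (names(df)[1] != "animal_id")
      stop_ld("genotype TSV must start with an 'animal_id' column")
    ids <- df[[1]]
    snp_ids <- names(df)[-1]
    codes <- as.matrix(df[, -1, drop = FALSE])
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            colClasses = "character")
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(lead %in% names(df)[seq_len(6)]))
      stop_ld("not a PLINK .raw file: expected leading columns %s",
              paste(lead, collapse = " "))
    ids <- df[["IID"]]
    gcols <- setdiff(names(df), lead)
    snp_ids <- sub("_[ACGT0-9]+$", "", gcols)
    codes <- as.matrix(df[, gcols, drop = FALSE])
    colnames(codes) <- snp_ids
  }
  suppressWarnings(storage.mode(codes) <- "numeric")
  codes[codes == ""] <- NA
  bad <- which(!(codes %in% c(0, 1, 2)) & !is.na(codes))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(codes))
    stop_ld("invalid genotype code at animal '%s', SNP '%s' (line %d)",
            ids[rc[1]], snp_ids[rc[2]], rc[1] + 1L)
  }
  n_missing <- sum(is.na(codes))
  if (n_missing > 0) {
    if (!impute_missing)
      stop_ld("%d missing genotype code(s); set impute_missing = TRUE",
              n_missing)
    for (j in which(colSums(is.na(codes)) > 0)) {
      m <- codes[, j]
      if (all(is.na(m))) stop_ld("SNP '%s' entirely missing", snp_ids[j])
      codes[is.na(m), j] <- round(mean(m, na.rm = TRUE))
    }
    message(sprintf("imputed %d missing genotype code(s)", n_missing))
  }
  map <- read_map(map_path)
  storage.mode(codes) <- "integer"
  genotype_matrix(codes, ids, snp_ids, map)
}

#' Write / read a SNP map TSV (`snp_id`, `chrom`, `pos`)
#'
#' @param map map data.frame; `pos` is a 1-based bp position.
#' @param path file path.
#' @export
write_map <- function(map, path) {
  utils::write.table(map[, c("snp_id", "chrom", "pos")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop_ld("no such map file: %s", path)
  map <- utils::read.delim(path)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop_ld("map file %s must have columns: %s", path,
            paste(need, collapse = ", "))
  if (any(!is.finite(map$pos) | map$pos < 1))
    stop_ld("map positions must be 1-based integers (file %s)", path)
  map$snp_id <- as.character(map$snp_id)
  map
}

#' Write / read a phenotype table TSV
#'
#' Columns `animal_id`, `trait`, `value`, `record_count`, `birth_year`;
#' one row per animal x trait.
#'
#' @param phenotypes data.frame in that layout.
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  need <- c("animal_id", "trait", "value", "record_count", "birth_year")
  if (!all(need %in% names(phenotypes)))
    stop_ld("phenotype table needs columns: %s", paste(need, collapse = ", "))
  utils::write.table(phenotypes[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_ld("no such file: %s", path)
  df <- utils::read.delim(path)
  need <- c("animal_id", "trait", "value", "record_count", "birth_year")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ld("phenotype file missing column(s): %s",
                            paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$record_count) | df$record_count < 1)
  if (length(bad))
    stop_ld("record_count < 1 at line %d", bad[1] + 1L)
  dup <- duplicated(df[, c("animal_id", "trait")])
  if (any(dup))
    stop_ld("duplicate (animal, trait) row at line %d", which(dup)[1] + 1L)
  df$animal_id <- as.character(df$animal_id)
  df
}

#' Write / read a pedigree CSV
#'
#' Columns `animal`, `sire`, `dam`, `birth_year`; unknown parents are
#' written as `0` and read back as `NA`. Reading validates acyclicity.
#'
#' @param pedigree data.frame in that layout (`NA` for unknown parents).
#' @param path file path.
#' @param unknown token representing an unknown parent on disk.
#' @export
write_pedigree <- function(pedigree, path, unknown = "0") {
  need <- c("animal", "sire", "dam", "birth_year")
  if (!all(need %in% names(pedigree)))
    stop_ld("pedigree needs columns: %s", paste(need, collapse = ", "))
  out <- pedigree[, need]
  out$sire[is.na(out$sire)] <- unknown
  out$dam[is.na(out$dam)] <- unknown
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path, unknown = "0") {
  if (!file.exists(path)) stop_ld("no such file: %s", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("animal", "sire", "dam", "birth_year")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ld("pedigree file missing column(s): %s",
                            paste(miss, collapse = ", "))
  df$sire[df$sire %in% c(unknown, "", "NA")] <- NA
  df$dam[df$dam %in% c(unknown, "", "NA")] <- NA
  df$birth_year <- as.integer(df$birth_year)
  if (anyDuplicated(df$animal))
    stop_ld("duplicate animal id '%s'", df$animal[duplicated(df$animal)][1])
  topo_order_pedigree(df)  # errors on cycles (incl. animal as own parent)
  df
}

#' Write / read a ranked SNP list TSV
#'
#' Columns `rank`, `snp_id`, `trait`, `method`, `elimination_step`,
#' `abs_coef`.
#'
#' @param ranked a `ranked_list`.
#' @param path file path.
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  df <- ranked$entries
  df$trait <- ranked$trait
  df$method <- ranked$method
  utils::write.table(
    df[, c("rank", "snp_id", "trait", "method", "elimination_step",
           "abs_coef")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, colClasses = list(snp_id = "character"))
  need <- c("rank", "snp_id", "trait", "method")
  if (!all(need %in% names(df)))
    stop_ld("ranked list missing column(s): %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[order(df$rank), ]
  if (!identical(as.integer(df$rank), seq_len(nrow(df))))
    stop_ld("ranks are not contiguous from 1")
  if (!"elimination_step" %in% names(df)) df$elimination_step <- NA_integer_
  if (!"abs_coef" %in% names(df)) df$abs_coef <- NA_real_
  structure(list(trait = df$trait[1], method = df$method[1],
                 entries = df[, c("rank", "snp_id", "elimination_step",
                                  "abs_coef")],
                 steps = NULL, final_effects = NULL),
            class = "ranked_list")
}

#' Write / read a SNP subset (one snp_id per line + JSON sidecar)
#'
#' @param subset a `subset_spec`.
#' @param path subset TSV path; the sidecar goes to `<path>.json`.
#' @export
write_subset <- function(subset, path) {
  stopifnot(inherits(subset, "subset_spec"))
  writeLines(c("snp_id", subset$snp_ids), path)
  side <- subset[c("strategy", "n_requested", "n_actual", "provenance")]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_subset
#' @export
read_subset <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "snp_id") stop_ld("subset file must start with 'snp_id'")
  ids <- lines[-1]
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    spec <- new_subset_spec(side$strategy, side$n_requested, ids,
                            side$provenance)
  } else {
    spec <- new_subset_spec("unknown", length(ids), ids, "file")
  }
  spec
}

#' Write / read marker effects (TSV + JSON sidecar)
#'
#' The TSV has columns `snp_id`, `coefficient`; the sidecar records the
#' method, intercept, hyperparameter and centering means.
#'
#' @param effects a `marker_effects`.
#' @param path effects TSV path; sidecar at `<path>.json`.
#' @export
write_effects <- function(effects, path) {
  stopifnot(inherits(effects, "marker_effects"))
  utils::write.table(
    data.frame(snp_id = names(effects$coefficients),
               coefficient = as.numeric(effects$coefficients)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(method = effects$method, intercept = effects$intercept,
               hyperparameter = effects$hyperparameter,
               centering = as.list(effects$centering))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  df <- utils::read.delim(path, colClasses = list(snp_id = "character"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  coef <- stats::setNames(df$coefficient, df$snp_id)
  centering <- if (length(side$centering)) unlist(side$centering) else NULL
  marker_effects(side$method, side$intercept, coef, side$hyperparameter,
                 centering = centering)
}
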