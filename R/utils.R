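#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from a single integer seed. Named
#' sub-streams (pedigree, haplotypes, effects, noise, folds, ...) get their
#' own derived seeds so that individual stages can be re-run in isolation
#' and still reproduce bit-identically.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return An integer seed in [0, 2^31 - 1), a deterministic function of
#'   `(seed, stream)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

ld_log <- function(..., verbose = getOption("ldpanel.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}

stop_ld <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
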