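# Selection-index definitions used by the Australian dairy industry.
# Component traits enter as breeding values (ABV); the indices are fixed
# linear combinations with the published economic weights.

#' Published selection-index weights
#'
#' Economic weights of the Australian Selection Index (ASI), the survival
#' index, and the Australian Profit Ranking (APR). ASI combines the milk
#' production components; APR extends ASI with workability, survival,
#' health and fertility components. The survival component of APR is itself
#' the survival index, which must be computed first.
#'
#' @format A named list of named numeric vectors (component trait -> weight).
#' @export
index_weights <- list(
  asi = c(protein = 3.8, fat = 0.9, milk = -0.048),
  survival = c(likeability = 0.5, overall_type = 1.8,
               udder_depth = 3.0, pin_set = 2.2),
  apr = c(protein = 3.8, fat = 0.9, milk = -0.048,
          milking_speed = 1.2, temperament = 2.0, survival = 3.9,
          cell_count = 0.34, live_weight = -0.26, daughter_fertility = 3.0)
)

#' Define a trait
#'
#' A trait is either `direct` (simulated with its own QTL architecture and
#' heritability) or an `index` (a deterministic weighted sum of component
#' trait values).
#'
#' @param name trait label.
#' @param kind `"direct"` or `"index"`.
#' @param h2 narrow-sense heritability in `[0, 1]` (direct traits).
#' @param index_weights named numeric vector, component trait -> weight
#'   (index traits; empty for direct traits).
#' @return A `trait_definition` object.
#' @examples
#' trait_definition("protein", h2 = 0.3)
#' trait_definition("asi", kind = "index", index_weights = index_weights$asi)
#' @export
trait_definition <- function(name, kind = c("direct", "index"), h2 = NA_real_,
                             index_weights = numeric()) {
  kind <- match.arg(kind)
  if (kind == "direct") {
    if (!is.finite(h2) || h2 < 0 || h2 > 1)
      stop_ld("trait '%s': h2 must lie in [0, 1], got %s", name, h2)
  } else {
    if (length(index_weights) == 0 || is.null(names(index_weights)))
      stop_ld("index trait '%s' needs a named weight vector", name)
  }
  structure(list(name = name, kind = kind, h2 = h2,
                 index_weights = index_weights),
            class = "trait_definition")
}

#' Evaluate a selection index
#'
#' Computes the weighted sum of component trait values with the index's
#' published weights, e.g. ASI = 3.8 x protein + 0.9 x fat - 0.048 x milk.
#' Components may be scalars or per-animal vectors (all the same length).
#'
#' @param components named list or named numeric vector of component values.
#' @param definition a `trait_definition` of kind `"index"`.
#' @return Numeric value(s) of the index.
#' @examples
#' asi <- trait_definition("asi", kind = "index",
#'                         index_weights = index_weights$asi)
#' compute_index(c(protein = 10, fat = 10, milk = 100), asi)  # 42.2
#' @export
compute_index <- function(components, definition) {
  stopifnot(inherits(definition, "trait_definition"))
  if (definition$kind != "index")
    stop_ld("'%s' is not an index trait", definition$name)
  w <- definition$index_weights
  missing <- setdiff(names(w), names(components))
  if (length(missing))
    stop_ld("index '%s': missing component(s): %s",
            definition$name, paste(missing, collapse = ", "))
  vals <- lapply(names(w), function(nm) components[[nm]])
  lens <- vapply(vals, length, 1L)
  if (length(unique(lens)) != 1L)
    stop_ld("index '%s': component lengths differ", definition$name)
  out <- 0
  for (i in seq_along(w)) out <- out + w[[i]] * vals[[i]]
  unname(out)
}

#' Standard trait set of the dairy study design
#'
#' Convenience constructor for the component traits and the three indices
#' (ASI, survival, APR). Heritabilities for the named production and type
#' traits follow published dairy estimates (protein % 0.56, fat % 0.52,
#' milk yield 0.28, overall type 0.18, survival components 0.03); unnamed
#' components default to `h2_other`.
#'
#' @param h2_other heritability assigned to components without a published
#'   estimate (workability, health, fertility components).
#' @return Named list of `trait_definition` objects; indices last, ordered
#'   so each index's components precede it.
#' @export
standard_traits <- function(h2_other = 0.1) {
  h2 <- c(protein = 0.56, fat = 0.52, milk = 0.28,
          overall_type = 0.18, likeability = 0.03, udder_depth = 0.18,
          pin_set = 0.18)
  comps <- unique(c(names(index_weights$asi), names(index_weights$survival),
                    setdiff(names(index_weights$apr), "survival")))
  out <- list()
  for (nm in comps) {
    out[[nm]] <- trait_definition(
      nm, h2 = if (nm %in% names(h2)) h2[[nm]] else h2_other)
  }
  out$asi <- trait_definition("asi", "index", index_weights = index_weights$asi)
  out$survival <- trait_definition("survival", "index",
                                   index_weights = index_weights$survival)
  out$apr <- trait_definition("apr", "index", index_weights = index_weights$apr)
  out
}
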