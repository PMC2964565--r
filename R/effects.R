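# Marker-effects container shared by both engines, and DGV prediction.

#' Construct a marker-effects object
#'
#' Holds the fitted prediction equation of either engine: intercept,
#' per-SNP coefficients on the 0/1/2 dosage scale, and the fitted
#' hyperparameter (ridge penalty or number of latent components).
#'
#' @param method `"rr"` or `"plsr"`.
#' @param intercept fitted intercept.
#' @param coefficients named numeric vector of per-SNP effects.
#' @param hyperparameter `lambda` (rr) or `n_components` (plsr).
#' @param centering per-SNP training means used for centering (`NULL` for
#'   rr, which fits raw dosages with an explicit intercept).
#' @param extra list of method-specific diagnostics.
#' @return A `marker_effects` object.
#' @export
marker_effects <- function(method, intercept, coefficients, hyperparameter,
                           centering = NULL, extra = list()) {
  stopifnot(method %in% c("rr", "plsr"))
  structure(c(list(method = method, intercept = intercept,
                   coefficients = coefficients,
                   hyperparameter = hyperparameter, centering = centering),
              extra),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  hp <- if (x$method == "rr") sprintf("lambda = %.4g", x$hyperparameter)
        else sprintf("%d component(s)", x$hyperparameter)
  cat(sprintf("marker_effects [%s]: %d SNP, intercept %.4g, %s\n",
              x$method, length(x$coefficients), x$intercept, hp))
  invisible(x)
}

#' Predict direct genomic values
#'
#' DGV = X b-hat on the training coding convention. The intercept is
#' excluded: accuracy is measured by correlation, which is shift-invariant,
#' and omitting it keeps rr and plsr DGV on the same relative scale.
#'
#' @param X_new a `genotype_matrix` (or plain matrix with SNP column names)
#'   of the animals to predict. Its SNP set must match the effects' SNP set
#'   exactly; order is normalized internally.
#' @param effects a `marker_effects` object.
#' @return Named numeric vector of DGV, one per animal.
#' @export
predict_dgv <- function(X_new, effects) {
  stopifnot(inherits(effects, "marker_effects"))
  M <- as_code_matrix(X_new)
  storage.mode(M) <- "double"
  ids <- names(effects$coefficients)
  cn <- if (inherits(X_new, "genotype_matrix")) X_new$snp_ids else colnames(M)
  if (!is.null(ids) && !is.null(cn)) {
    missing <- setdiff(ids, cn)
    extra <- setdiff(cn, ids)
    if (length(missing) || length(extra))
      stop_ld("SNP mismatch: missing [%s], extra [%s]",
              paste(utils::head(missing, 5), collapse = ", "),
              paste(utils::head(extra, 5), collapse = ", "))
    M <- M[, ids, drop = FALSE]
  } else if (ncol(M) != length(effects$coefficients)) {
    stop_ld("X_new has %d SNP but effects have %d (and no ids to match on)",
            ncol(M), length(effects$coefficients))
  }
  dgv <- as.numeric(M %*% effects$coefficients)
  names(dgv) <- if (inherits(X_new, "genotype_matrix")) X_new$animal_ids
                else rownames(M)
  dgv
}

#' Fitted values on the training scale
#'
#' Unlike [predict_dgv()], includes the intercept (and, for plsr, the
#' centering correction already absorbed into it), so the result is on the
#' phenotype scale.
#'
#' @inheritParams predict_dgv
#' @return Numeric vector of fitted phenotype values.
#' @export
predict_response <- function(X_new, effects) {
  effects$intercept + predict_dgv(X_new, effects)
}
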