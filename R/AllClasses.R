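#' TaxonAreaMatrix: a binary area-by-species occurrence matrix
#'
#' The single input object of the package: rows are geographic (floristic)
#' areas, columns are species, and each cell records presence (1) or absence
#' (0) of the species in the area.  No missing or polymorphic states are
#' allowed; the downstream Mk machinery assumes fully observed tips.
#'
#' @slot cells integer matrix of 0/1 values with unique, non-empty rownames
#'   (areas) and colnames (species).
#' @slot provenance free-text tag recording where the matrix came from.
#'
#' @seealso [taxonAreaMatrix()] for the user-facing constructor,
#'   [readTaxonAreaMatrix()] to read one from CSV/TSV/NEXUS.
#' @exportClass TaxonAreaMatrix
setClass("TaxonAreaMatrix",
         representation(cells = "matrix", provenance = "character"))

setValidity("TaxonAreaMatrix", function(object) {
  m <- object@cells
  msgs <- character()
  if (!is.numeric(m) && !is.integer(m))
    msgs <- c(msgs, "cells must be a numeric 0/1 matrix")
  if (is.null(rownames(m)) || (ncol(m) > 0L && is.null(colnames(m))))
    msgs <- c(msgs, "cells must have area rownames and species colnames")
  rn <- rownames(m); cn <- colnames(m)
  if (!is.null(rn)) {
    if (anyDuplicated(rn)) msgs <- c(msgs, sprintf(
      "duplicate area names: %s", paste(unique(rn[duplicated(rn)]), collapse = ", ")))
    if (any(!nzchar(rn))) msgs <- c(msgs, "empty area name")
  }
  if (!is.null(cn) && ncol(m) > 0L) {
    if (anyDuplicated(cn)) msgs <- c(msgs, sprintf(
      "duplicate species names: %s", paste(unique(cn[duplicated(cn)]), collapse = ", ")))
    if (any(!nzchar(cn))) msgs <- c(msgs, "empty species name")
  }
  if (length(m) > 0L) {
    bad <- which(!(m %in% c(0, 1)))
    if (length(bad)) {
      i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
      j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
      msgs <- c(msgs, sprintf(
        "non-binary state '%s' at area '%s', character %d ('%s')",
        as.character(m[bad[1L]]), rn[i], j, cn[j]))
    }
  }
  if (length(object@provenance) != 1L)
    msgs <- c(msgs, "provenance must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' MkModel: parameters of the symmetric binary Mk(+G+I) model
#'
#' A two-state continuous-time Markov model with equal gain (0 to 1) and loss
#' (1 to 0) rates and uniform stationary frequencies (1/2, 1/2).  The overall
#' rate is fixed at 1 by normalisation; rate heterogeneity across characters
#' is modelled by a discretised Gamma(alpha, alpha) distribution with unit
#' mean (`gammaShape`), optionally mixed with a class of strictly invariant
#' characters of proportion `pInvariant`.
#'
#' @slot gammaShape positive shape alpha of the discrete-gamma rate mixture,
#'   or `NA_real_` for a rate-homogeneous model.
#' @slot nCategories number of equal-probability gamma rate categories
#'   (ignored when `gammaShape` is `NA`).
#' @slot pInvariant proportion of invariant characters in `[0, 1)`.
#'
#' @seealso [mkModel()], [gammaCategoryRates()], [transitionProbability()]
#' @exportClass MkModel
setClass("MkModel",
         representation(gammaShape = "numeric", nCategories = "integer",
                        pInvariant = "numeric"))

setValidity("MkModel", function(object) {
  msgs <- character()
  a <- object@gammaShape
  if (length(a) != 1L) msgs <- c(msgs, "gammaShape must be length 1")
  else if (!is.na(a) && a <= 0) msgs <- c(msgs, "gammaShape must be > 0")
  k <- object@nCategories
  if (length(k) != 1L || is.na(k) || k < 1L)
    msgs <- c(msgs, "nCategories must be a positive integer")
  p <- object@pInvariant
  if (length(p) != 1L || is.na(p) || p < 0 || p >= 1)
    msgs <- c(msgs, "pInvariant must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})
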