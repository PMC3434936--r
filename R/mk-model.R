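#' Construct a binary Mk model
#'
#' @param gammaShape positive gamma shape alpha for among-character rate
#'   heterogeneity, or `NULL`/`NA` for a homogeneous model.
#' @param nCategories number of discrete gamma categories (default 4, the
#'   convention of mainstream likelihood programs).
#' @param pInvariant proportion of invariant characters in `[0, 1)`
#'   (`+I` mixture component; default 0).
#' @return an [MkModel-class].
#' @examples
#' mkModel()                    # plain Mk
#' mkModel(gammaShape = 0.5)    # Mk+G
#' mkModel(0.5, pInvariant = .1)  # Mk+G+I
#' @export
mkModel <- function(gammaShape = NULL, nCategories = 4L, pInvariant = 0) {
  if (is.null(gammaShape)) gammaShape <- NA_real_
  methods::new("MkModel", gammaShape = as.numeric(gammaShape),
               nCategories = as.integer(nCategories),
               pInvariant = as.numeric(pInvariant))
}

setMethod("show", "MkModel", function(object) {
  cat("Binary Mk model (symmetric rates, uniform stationary frequencies)\n")
  if (is.na(object@gammaShape)) cat("  rate heterogeneity: none\n")
  else cat(sprintf("  discrete gamma: alpha = %g, %d categories\n",
                   object@gammaShape, object@nCategories))
  if (object@pInvariant > 0)
    cat(sprintf("  invariant class: p = %g\n", object@pInvariant))
  invisible(object)
})

#' Discrete-gamma category rates
#'
#' Mean rates of `k` equal-probability quantile classes of a
#' `Gamma(alpha, alpha)` distribution (unit mean).  The class mean is
#' computed in closed form from the incomplete-gamma identity
#' `E[X; X in (a,b)] = P(G(alpha+1, alpha) <= b) - P(G(alpha+1, alpha) <= a)`.
#'
#' @param alpha positive shape parameter.
#' @param k number of categories.
#' @return numeric vector of `k` rates averaging 1.
#' @export
gammaCategoryRates <- function(alpha, k = 4L) {
  stopifnot(is.finite(alpha), alpha > 0, k >= 1L)
  if (k == 1L) return(1)
  cuts <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha,
                        rate = alpha)
  upper <- stats::pgamma(cuts[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(cuts[-(k + 1L)], shape = alpha + 1, rate = alpha)
  r <- (upper - lower) * k
  r / mean(r)   # guard against residual numeric drift; rates must average 1
}

#' Two-state transition probability matrix
#'
#' Closed form for the symmetric binary Mk chain with unit base rate:
#' `P(same) = (1 + exp(-2rt))/2`, `P(different) = (1 - exp(-2rt))/2`.
#'
#' @param t branch length (expected changes per character at rate 1), `>= 0`.
#' @param rate positive rate multiplier `r`.
#' @return a 2x2 stochastic matrix with rows/columns named `"0"`, `"1"`.
#' @export
transitionProbability <- function(t, rate = 1) {
  if (length(t) != 1L || is.na(t) || t < 0) stop("branch length must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  e <- exp(-2 * rate * t)
  ps <- (1 + e) / 2
  pd <- (1 - e) / 2
  matrix(c(ps, pd, pd, ps), 2L, 2L, dimnames = list(c("0", "1"), c("0", "1")))
}

# rate classes (rates + weights) implied by an MkModel; the invariant class
# has rate 0 and weight pInvariant, gamma classes share the remaining weight
.rateClasses <- function(model) {
  if (is.na(model@gammaShape)) { rates <- 1; w <- 1 }
  else {
    rates <- gammaCategoryRates(model@gammaShape, model@nCategories)
    w <- rep(1 / length(rates), length(rates))
  }
  p <- model@pInvariant
  if (p > 0) { rates <- c(0, rates); w <- c(p, (1 - p) * w) }
  list(rates = rates, weights = w)
}
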