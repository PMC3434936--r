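#' Append hypothetical extinct taxa (all-zero columns)
#'
#' Adds `n` all-zero species columns representing members of an unknown
#' palaeoflora absent from every area.  Such columns are cost-free under
#' parsimony (constant characters) but informative under the Mk likelihood,
#' which is the keystone contrast the augmentation scenarios exploit.
#'
#' @param x a [TaxonAreaMatrix-class].
#' @param n number of columns to append (`>= 0`).
#' @param prefix name prefix for the generated columns.
#' @return the augmented matrix; original columns untouched.
#' @export
addExtinctTaxa <- function(x, n, prefix = "EXTINCT_") {
  stopifnot(methods::is(x, "TaxonAreaMatrix"), n >= 0)
  if (n == 0) return(x)
  newNames <- sprintf("%s%d", prefix, seq_len(n))
  clash <- intersect(newNames, speciesNames(x))
  if (length(clash))
    stop("extinct-taxon name collision: ", paste(clash[1:min(3, length(clash))],
                                                 collapse = ", "))
  m <- presence(x)
  ext <- matrix(0L, nrow(m), n, dimnames = list(rownames(m), newNames))
  taxonAreaMatrix(cbind(m, ext), provenance = provenance(x))
}

#' Run the extinct-taxa augmentation scenario battery
#'
#' For each fraction `f`, appends `round(f * nSpecies)` (half-up) all-zero
#' columns, adds the all-zero artificial outgroup, runs the ML search and
#' fit, and records the log-likelihood and the Robinson-Foulds distance to
#' the baseline (`f = 0`) tree.  Each scenario draws its seed as
#' `seed + index`, so the whole battery is reproducible from one seed.
#'
#' @param x a [TaxonAreaMatrix-class] (without outgroup).
#' @param fractions extinct-to-extant ratios; the defaults reproduce the
#'   509/1018/1527/2036-column designs for a 1018-species matrix.
#' @param gamma,invariant,nCategories Mk model flags.
#' @param nStarts,swap,mlControl search settings per scenario (see
#'   [treeSearch()]).
#' @param B bootstrap replicates per scenario (0 = skip bootstrap).
#' @param seed integer seed for the battery.
#' @param outgroupName name for the artificial outgroup area.
#' @return object of class `scenarioBattery`: list of per-scenario results
#'   (`nExtinct`, `tree`, `logLik`, `alpha`, `rfToBaseline`, `search`), with
#'   the baseline (`f = 0`) first.
#' @export
runScenarios <- function(x, fractions = c(0.5, 1, 1.5, 2), gamma = TRUE,
                         invariant = FALSE, nCategories = 4L,
                         nStarts = 5L, swap = c("spr", "nni"), B = 0L,
                         seed = 1L, outgroupName = "ROOT",
                         mlControl = list()) {
  stopifnot(methods::is(x, "TaxonAreaMatrix"), all(fractions >= 0))
  swap <- match.arg(swap)
  nsp <- length(speciesNames(x))
  levels <- c(0, fractions)
  results <- vector("list", length(levels))
  baselineTree <- NULL
  for (i in seq_along(levels)) {
    f <- levels[i]
    n <- floor(f * nsp + 0.5)                 # round half up: 0.5*1018 -> 509
    xi <- addExtinctTaxa(x, n)
    xi <- addAllZeroOutgroup(xi, outgroupName)
    sr <- if (B > 0)
      bootstrapSearch(xi, objective = "likelihood", B = B, gamma = gamma,
                      invariant = invariant, nCategories = nCategories,
                      nStarts = nStarts, swap = swap, seed = seed + i - 1L)
    else
      treeSearch(xi, objective = "likelihood", gamma = gamma,
                 invariant = invariant, nCategories = nCategories,
                 nStarts = nStarts, swap = swap, seed = seed + i - 1L,
                 mlControl = mlControl)
    tr <- sr$best
    if (i == 1L) baselineTree <- tr
    results[[i]] <- list(
      fraction = f, nExtinct = as.integer(n), tree = tr,
      logLik = sr$score, alpha = sr$fit$alpha,
      rfToBaseline = rfDistance(tr, baselineTree),
      search = sr)
  }
  structure(results, class = "scenarioBattery")
}

#' @export
print.scenarioBattery <- function(x, ...) {
  cat("Extinct-taxa augmentation scenarios:\n")
  for (r in x)
    cat(sprintf("  +%5d all-zero columns: lnL = %12.4f  RF to baseline = %d\n",
                r$nExtinct, r$logLik, r$rfToBaseline))
  invisible(x)
}
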