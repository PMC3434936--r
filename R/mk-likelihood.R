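# Felsenstein pruning for the symmetric binary Mk model, with gamma/invariant
# rate mixtures.  Characters are compressed to unique site patterns first.

.compressPatterns <- function(m) {
  if (ncol(m) == 0L)
    return(list(pat = m, weights = numeric(0), index = integer(0)))
  key <- apply(m, 2L, paste, collapse = "")
  keep <- !duplicated(key)
  pat <- m[, keep, drop = FALSE]
  index <- match(key, key[keep])
  list(pat = pat, weights = as.numeric(tabulate(index, sum(keep))),
       index = index)
}

# per-pattern likelihoods for one rate class in plain R; retained as the
# reference path for the compiled kernel (cross-checked in the tests).
# pat rows must be ordered as po$tip.label where po is the postorder tree
.patternLik <- function(po, pat, rate) {
  E <- po$edge; el <- po$edge.length
  nt <- length(po$tip.label)
  nn <- nt + po$Nnode
  npat <- ncol(pat)
  L0 <- matrix(NA_real_, nn, npat)
  L1 <- matrix(NA_real_, nn, npat)
  L0[seq_len(nt), ] <- (pat == 0)
  L1[seq_len(nt), ] <- (pat == 1)
  touched <- rep(FALSE, nn)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    ee <- exp(-2 * rate * el[e])
    ps <- (1 + ee) / 2; pd <- (1 - ee) / 2
    m0 <- ps * L0[ch, ] + pd * L1[ch, ]
    m1 <- pd * L0[ch, ] + ps * L1[ch, ]
    if (touched[p]) { L0[p, ] <- L0[p, ] * m0; L1[p, ] <- L1[p, ] * m1 }
    else { L0[p, ] <- m0; L1[p, ] <- m1; touched[p] <- TRUE }
  }
  root <- E[nrow(E), 1L]
  0.5 * (L0[root, ] + L1[root, ])
}

.siteLikInternal <- function(po, pat, model) {
  rc <- .rateClasses(model)
  storage.mode(pat) <- "integer"
  .mkSiteLikC(po$edge, po$edge.length, length(po$tip.label), pat,
              rc$rates, rc$weights)
}

# pure-R equivalent of .siteLikInternal, for validation
.siteLikR <- function(po, pat, model) {
  rc <- .rateClasses(model)
  sl <- numeric(ncol(pat))
  for (k in seq_along(rc$rates))
    sl <- sl + rc$weights[k] * .patternLik(po, pat, rc$rates[k])
  sl
}

#' Mk log-likelihood of a matrix on a fixed tree
#'
#' Felsenstein-pruning log-likelihood of all characters under the symmetric
#' binary Mk model, marginalising the root over the uniform stationary
#' frequencies (1/2, 1/2).  Rate heterogeneity (discrete gamma) and an
#' invariant-character class are mixed per character according to `model`.
#' Constant (all-zero / all-one) characters contribute like any other: no
#' ascertainment correction is applied, which is what makes all-zero
#' "extinct taxa" columns informative under likelihood.
#'
#' @param tree `phylo` with branch lengths set on every edge; rooted or
#'   unrooted (the reversible model makes the likelihood rooting-invariant).
#' @param x a [TaxonAreaMatrix-class] whose areas are the tree's tips.
#' @param model an [MkModel-class] (default: no heterogeneity).
#' @return object of class `mkLik`: list with `logLik` (natural log),
#'   `siteLogLik` (per character, named by species), `model`, `tree`.
#' @examples
#' tr <- readAreaTree("(A:0.25,B:0.25);")
#' m <- taxonAreaMatrix(rbind(A = c(0, 0), B = c(1, 0)),
#'                      species = c("sp1", "sp2"))
#' mkLogLik(tr, m)$logLik
#' @export
mkLogLik <- function(tree, x, model = mkModel()) {
  stopifnot(inherits(tree, "phylo"), methods::is(x, "TaxonAreaMatrix"),
            methods::is(model, "MkModel"))
  .checkTipsMatch(tree, x)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("all branch lengths must be set before computing the likelihood")
  po <- ape::reorder.phylo(tree, "postorder")
  m <- presence(x)
  cp <- .compressPatterns(m[po$tip.label, , drop = FALSE])
  sl <- .siteLikInternal(po, cp$pat, model)
  siteLogLik <- log(sl)[cp$index]
  names(siteLogLik) <- speciesNames(x)
  structure(list(logLik = sum(siteLogLik), siteLogLik = siteLogLik,
                 model = model, tree = tree),
            class = "mkLik")
}

#' @export
print.mkLik <- function(x, ...) {
  cat(sprintf("Mk log-likelihood: %.6f  (-lnL = %.6f, %d characters)\n",
              x$logLik, -x$logLik, length(x$siteLogLik)))
  invisible(x)
}
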