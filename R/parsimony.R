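# Fitch parsimony on binary characters, with ensemble CI/RI and Sankoff-style
# ancestral state sets.  State sets are bit-encoded: 1 = {0}, 2 = {1}, 3 = {0,1}.

# normalise to a fully binary rooted tree; a single basal trifurcation (the
# unrooted representation) is resolved by rooting on its first tip, anything
# else is refused
.asBinaryRooted <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) stop(
    "polytomy in tree: resolve it before computing parsimony scores")
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
  tree
}

.checkTipsMatch <- function(tree, x) {
  if (!setequal(tree$tip.label, areaNames(x)))
    stop("tree tips and matrix areas differ: tree-only {",
         paste(setdiff(tree$tip.label, areaNames(x)), collapse = ","),
         "}, matrix-only {",
         paste(setdiff(areaNames(x), tree$tip.label), collapse = ","), "}")
  invisible(TRUE)
}

# first (uppass-free) Fitch pass over all characters at once
# returns list(sets = node x char matrix of bit sets, steps = per-char counts,
#              postorder tree)
.fitchPass <- function(tree, m) {
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  nt <- length(po$tip.label)
  nn <- nt + po$Nnode
  nchar_ <- ncol(m)
  m <- m[po$tip.label, , drop = FALSE]
  sets <- matrix(0L, nn, nchar_)
  sets[seq_len(nt), ] <- 1L + m
  steps <- numeric(nchar_)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    cs <- sets[ch, ]
    ps <- sets[p, ]
    if (all(ps == 0L)) sets[p, ] <- cs
    else {
      inter <- bitwAnd(ps, cs)
      disjoint <- inter == 0L
      steps <- steps + disjoint
      sets[p, ] <- ifelse(disjoint, bitwOr(ps, cs), inter)
    }
  }
  list(sets = sets, steps = steps, tree = po)
}

# tree length alone (no CI/RI bookkeeping); the search's inner loop
.fitchLengthOnly <- function(tree, x) {
  tree <- .asBinaryRooted(tree)
  .checkTipsMatch(tree, x)
  cp <- .compressPatterns(presence(x))
  fp <- .fitchPass(tree, cp$pat)
  as.integer(sum(fp$steps * cp$weights))
}

#' Fitch parsimony score of a tree
#'
#' Two-pass Fitch length on each binary character, with the per-character
#' decomposition needed for the ensemble consistency and retention indices.
#' The score is independent of rooting; trees given unrooted (one basal
#' trifurcation) are accepted, other polytomies are refused.
#'
#' @param tree resolved `phylo` whose tips are the areas of `x`.
#' @param x a [TaxonAreaMatrix-class].
#' @return an object of class `parsimonyScore`: a list with `length` (total
#'   steps `S`), `steps` (`s_i` per character), `minSteps` (`m_i`: 1 for
#'   variable characters), `maxSteps` (`g_i`: count of the rarer state),
#'   `ci`, `ri` (all variable characters) and `ciInformative`,
#'   `riInformative` (parsimony-informative characters only).
#' @seealso [ciRi()] for the index conventions.
#' @export
fitchScore <- function(tree, x) {
  stopifnot(methods::is(x, "TaxonAreaMatrix"))
  tree <- .asBinaryRooted(tree)
  .checkTipsMatch(tree, x)
  m <- presence(x)
  cp <- .compressPatterns(m)
  fp <- .fitchPass(tree, cp$pat)
  steps <- fp$steps[cp$index]
  n1 <- colSums(m); n0 <- nrow(m) - n1
  minSteps <- as.numeric(n1 > 0 & n0 > 0)
  maxSteps <- pmin(n0, n1)
  S <- sum(steps)
  idx <- ciRi(steps, minSteps, maxSteps)
  informative <- maxSteps >= 2
  idxInf <- if (any(informative))
    suppressWarnings(ciRi(steps[informative], minSteps[informative],
                          maxSteps[informative]))
  else list(ci = NA_real_, ri = NA_real_)
  structure(list(length = as.integer(S), steps = steps,
                 minSteps = minSteps, maxSteps = maxSteps,
                 ci = idx$ci, ri = idx$ri,
                 ciInformative = idxInf$ci, riInformative = idxInf$ri),
            class = "parsimonyScore")
}

#' @export
print.parsimonyScore <- function(x, ...) {
  cat(sprintf("Parsimony score: length = %d, CI = %.3f, RI = %.3f\n",
              x$length, x$ci, x$ri))
  cat(sprintf("  (informative characters only: CI = %.3f, RI = %.3f)\n",
              x$ciInformative, x$riInformative))
  invisible(x)
}

#' Ensemble consistency and retention indices
#'
#' `CI = sum(m_i) / S` and `RI = (sum(g_i) - S) / (sum(g_i) - sum(m_i))`,
#' where `s_i` are observed steps, `m_i` the per-character minima and `g_i`
#' the per-character maxima (count of the rarer state on a binary character).
#' Degenerate cases follow the usual reporting convention: `S = 0` gives
#' `CI = 1` with a warning, `sum(g) = sum(m)` gives `RI = 1` with a warning.
#'
#' @param steps,minSteps,maxSteps per-character `s_i`, `m_i`, `g_i`.
#' @return list with elements `ci` and `ri`.
#' @export
ciRi <- function(steps, minSteps, maxSteps) {
  S <- sum(steps)
  ci <- if (S == 0) { warning("tree length is 0; CI undefined, reported as 1"); 1 }
        else sum(minSteps) / S
  denom <- sum(maxSteps) - sum(minSteps)
  ri <- if (denom <= 0) { warning("max = min steps; RI undefined, reported as 1"); 1 }
        else (sum(maxSteps) - S) / denom
  list(ci = ci, ri = ri)
}

#' Parsimony ancestral state sets (MP comparator)
#'
#' For one character, returns at each node the set of states that occur in at
#' least one most-parsimonious reconstruction (minimum-change labelling) of
#' the tree, computed by an up/down dynamic programme over change counts.
#'
#' @param tree resolved `phylo`.
#' @param states named 0/1 vector over the tips (e.g. one matrix column), or
#'   unnamed in `tree$tip.label` order.
#' @return list with `sets` (list over nodes `1..Ntip+Nnode` of sorted state
#'   vectors) and `length` (minimum number of changes).
#' @export
mpAncestralStates <- function(tree, states) {
  tree <- .asBinaryRooted(tree)
  nt <- length(tree$tip.label)
  if (!is.null(names(states))) states <- states[tree$tip.label]
  if (length(states) != nt || anyNA(states) || !all(states %in% c(0, 1)))
    stop("states must be a 0/1 vector over all tips")
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  nn <- nt + po$Nnode
  up <- matrix(Inf, nn, 2L)                       # up[v, s+1]
  up[cbind(seq_len(nt), states + 1L)] <- 0
  kidsOf <- split(E[, 2L], E[, 1L])
  for (v in unique(E[, 1L])) {                    # postorder parents
    acc <- c(0, 0)
    for (ch in kidsOf[[as.character(v)]]) {
      acc <- acc + c(min(up[ch, 1L], up[ch, 2L] + 1),
                     min(up[ch, 1L] + 1, up[ch, 2L]))
    }
    up[v, ] <- acc
  }
  root <- E[nrow(E), 1L]
  minLen <- min(up[root, ])
  down <- matrix(Inf, nn, 2L)
  down[root, ] <- 0
  for (e in rev(seq_len(nrow(E)))) {              # preorder
    p <- E[e, 1L]; v <- E[e, 2L]
    sibs <- setdiff(kidsOf[[as.character(p)]], v)
    sibCost <- c(0, 0)
    for (b in sibs)
      sibCost <- sibCost + c(min(up[b, 1L], up[b, 2L] + 1),
                             min(up[b, 1L] + 1, up[b, 2L]))
    base <- down[p, ] + sibCost                   # indexed by parent state
    down[v, 1L] <- min(base[1L], base[2L] + 1)
    down[v, 2L] <- min(base[1L] + 1, base[2L])
  }
  total <- up + down
  sets <- lapply(seq_len(nn), function(v)
    (which(total[v, ] <= minLen + 1e-9) - 1L))
  list(sets = sets, length = as.integer(minLen))
}

# one arbitrary minimum-change reconstruction per character, used to seed
# branch lengths for likelihood optimisation; returns per-edge change counts
.parsimonyEdgeChanges <- function(tree, m) {
  fp <- .fitchPass(tree, m)
  po <- fp$tree; E <- po$edge; sets <- fp$sets
  nt <- length(po$tip.label)
  root <- E[nrow(E), 1L]
  state <- matrix(NA_integer_, nrow(sets), ncol(sets))
  state[root, ] <- ifelse(bitwAnd(sets[root, ], 1L) > 0L, 0L, 1L)
  changes <- numeric(nrow(E))
  for (e in rev(seq_len(nrow(E)))) {
    p <- E[e, 1L]; v <- E[e, 2L]
    ps <- state[p, ]
    inSet <- bitwAnd(sets[v, ], bitwShiftL(1L, ps)) > 0L
    state[v, ] <- ifelse(inSet, ps, ifelse(bitwAnd(sets[v, ], 1L) > 0L, 0L, 1L))
    changes[e] <- sum(state[v, ] != ps)
  }
  list(edge = E, changes = changes, tree = po)
}
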