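#' Heuristic area-tree search
#'
#' Stepwise random-addition starting trees followed by hill climbing over an
#' NNI or SPR neighbourhood, for the parsimony (tree length, minimised) or
#' likelihood (Mk lnL after branch-length optimisation, maximised) objective.
#' With fewer than four areas the trivial search space is enumerated exactly.
#' All randomness is governed by `seed`; for parsimony all equally optimal
#' topologies found (up to `maxSaved`) are retained, for likelihood the
#' single best tree is kept and fully re-optimised before returning.
#'
#' @param x a [TaxonAreaMatrix-class].
#' @param objective `"parsimony"` or `"likelihood"`.
#' @param gamma,invariant,nCategories Mk model flags for the likelihood
#'   objective (see [mkFit()]).
#' @param nStarts number of random-addition replicates.
#' @param maxSaved cap on equally parsimonious trees retained per search.
#' @param swap neighbourhood: `"spr"` (default) or `"nni"`.
#' @param seed integer seed; the result is reproducible from it.
#' @param mlControl `control` list passed to [mkFit()] during candidate
#'   scoring; by default candidates are scored at full tolerance so the
#'   search ranks topologies exactly as the final refit does (pass looser
#'   settings, e.g. `list(maxSweeps = 2, lbfgsMaxit = 40)`, to trade
#'   exactness for speed on larger problems).
#' @return object of class `treeSearch`: list with `trees` (a `multiPhylo`
#'   of optimal topologies, anchored rooted), `best` (first best tree; for
#'   likelihood with fitted branch lengths), `score` (tree length or lnL),
#'   `objective`, `fit` (the final [mkFit()] for likelihood), `nStarts`,
#'   `seed`.
#' @export
treeSearch <- function(x, objective = c("parsimony", "likelihood"),
                       gamma = TRUE, invariant = FALSE, nCategories = 4L,
                       nStarts = 20L, maxSaved = 100L,
                       swap = c("spr", "nni"), seed = NULL,
                       mlControl = list()) {
  stopifnot(methods::is(x, "TaxonAreaMatrix"))
  objective <- match.arg(objective)
  swap <- match.arg(swap)
  if (!is.null(seed)) set.seed(seed)
  n <- length(areaNames(x))
  if (n < 2L) stop("need at least two areas")

  scoreFun <- if (objective == "parsimony")
    function(tr) -.fitchLengthOnly(tr, x)      # larger = better throughout
  else
    function(tr) mkFit(tr, x, gamma = gamma, invariant = invariant,
                       nCategories = nCategories, control = mlControl)$logLik

  if (n < 4L) {
    tr <- if (n == 2L)
      ape::read.tree(text = sprintf("(%s,%s);",
        .nexusQuote(areaNames(x)[1L]), .nexusQuote(areaNames(x)[2L])))
    else .anchorRoot(ape::read.tree(text = sprintf("(%s,%s,%s);",
        .nexusQuote(areaNames(x)[1L]), .nexusQuote(areaNames(x)[2L]),
        .nexusQuote(areaNames(x)[3L]))), areaNames(x)[1L])
    return(.finishSearch(list(tr), scoreFun(tr), x, objective, gamma,
                         invariant, nCategories, nStarts, seed))
  }

  neighborFun <- if (swap == "spr") .sprNeighbors else .nniNeighbors
  bestScore <- -Inf
  bestTrees <- list(); bestKeys <- character(0)
  for (s in seq_len(nStarts)) {
    start <- .randomAdditionTree(x)
    if (objective == "parsimony") {
      res <- .plateauClimb(start, scoreFun, neighborFun, maxSaved)
    } else {
      res <- .simpleClimb(start, scoreFun, neighborFun)
    }
    if (res$score > bestScore + 1e-9) {
      bestScore <- res$score; bestTrees <- res$trees
      bestKeys <- vapply(bestTrees, .topoKey, character(1))
    } else if (objective == "parsimony" && abs(res$score - bestScore) <= 1e-9) {
      for (tr in res$trees) {
        k <- .topoKey(tr)
        if (!k %in% bestKeys && length(bestTrees) < maxSaved) {
          bestTrees <- c(bestTrees, list(tr)); bestKeys <- c(bestKeys, k)
        }
      }
    }
  }
  .finishSearch(bestTrees, bestScore, x, objective, gamma, invariant,
                nCategories, nStarts, seed)
}

# strict hill climbing keeping a single current tree
.simpleClimb <- function(tree, scoreFun, neighborFun) {
  cur <- tree; curScore <- scoreFun(cur)
  repeat {
    nb <- neighborFun(cur)
    if (!length(nb)) break
    scores <- vapply(nb, scoreFun, numeric(1))
    i <- which.max(scores)
    if (scores[i] > curScore + 1e-9) { cur <- nb[[i]]; curScore <- scores[i] }
    else break
  }
  list(trees = list(cur), score = curScore)
}

# hill climbing that also walks plateaus, collecting equally best trees
.plateauClimb <- function(tree, scoreFun, neighborFun, maxSaved) {
  curScore <- scoreFun(tree)
  saved <- list(tree); keys <- .topoKey(tree)
  frontier <- list(tree)
  while (length(frontier)) {
    t0 <- frontier[[1L]]; frontier <- frontier[-1L]
    nb <- neighborFun(t0)
    if (!length(nb)) next
    scores <- vapply(nb, scoreFun, numeric(1))
    if (max(scores) > curScore + 1e-9) {
      i <- which.max(scores)
      curScore <- scores[i]
      saved <- list(nb[[i]]); keys <- .topoKey(nb[[i]])
      frontier <- list(nb[[i]])
    } else {
      for (i in which(abs(scores - curScore) <= 1e-9)) {
        k <- .topoKey(nb[[i]])
        if (!k %in% keys && length(saved) < maxSaved) {
          saved <- c(saved, list(nb[[i]])); keys <- c(keys, k)
          frontier <- c(frontier, list(nb[[i]]))
        }
      }
    }
  }
  list(trees = saved, score = curScore)
}

.finishSearch <- function(trees, score, x, objective, gamma, invariant,
                          nCategories, nStarts, seed) {
  fit <- NULL
  best <- trees[[1L]]
  if (objective == "likelihood") {
    fit <- mkFit(best, x, gamma = gamma, invariant = invariant,
                 nCategories = nCategories)
    score <- fit$logLik
    best <- fit$tree
    trees <- list(best)
  } else score <- -score                        # back to tree length
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, best = best, score = score,
                 objective = objective, fit = fit,
                 nStarts = nStarts, seed = seed),
            class = "treeSearch")
}

#' @export
print.treeSearch <- function(x, ...) {
  lab <- if (x$objective == "parsimony") "tree length" else "lnL"
  cat(sprintf("Heuristic %s search: best %s = %.6f, %d optimal tree(s)\n",
              x$objective, lab, x$score, length(x$trees)))
  invisible(x)
}

#' Nonparametric bootstrap of an area-tree search
#'
#' Resamples species columns with replacement (`B` pseudo-matrices of the
#' original column count), reruns a reduced search on each, and maps the
#' bipartition frequencies (in percent) onto the best tree from the full
#' search.  Characters are the sampling units; areas are never resampled.
#'
#' @inheritParams treeSearch
#' @param B bootstrap replicate count.
#' @param bootStarts random-addition replicates per bootstrap search.
#' @param bootSwap neighbourhood for the bootstrap searches (NNI default:
#'   each replicate search is deliberately cheaper than the full one).
#' @return the `treeSearch` result of the full search, with `$best` carrying
#'   percentage supports in `$node.label` and an extra element
#'   `$bootTrees` (the replicate best trees).
#' @export
bootstrapSearch <- function(x, objective = c("parsimony", "likelihood"),
                            B = 100L, gamma = TRUE, invariant = FALSE,
                            nCategories = 4L, nStarts = 5L, bootStarts = 2L,
                            swap = c("spr", "nni"), bootSwap = "nni",
                            seed = NULL) {
  stopifnot(B >= 1L)
  objective <- match.arg(objective)
  swap <- match.arg(swap)
  if (!is.null(seed)) set.seed(seed)
  full <- treeSearch(x, objective = objective, gamma = gamma,
                     invariant = invariant, nCategories = nCategories,
                     nStarts = nStarts, swap = swap, seed = NULL)
  m <- presence(x)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    xb <- taxonAreaMatrix(m[, cols, drop = FALSE],
                          species = sprintf("bs%d", seq_along(cols)),
                          provenance = sprintf("bootstrap %d", b))
    reps[[b]] <- treeSearch(xb, objective = objective, gamma = gamma,
                            invariant = invariant, nCategories = nCategories,
                            nStarts = bootStarts, swap = bootSwap,
                            seed = NULL)$trees[[1L]]
  }
  class(reps) <- "multiPhylo"
  best <- full$best
  counts <- ape::prop.clades(best, reps, rooted = FALSE)
  pct <- round(100 * counts / B, 1)
  best$node.label <- ifelse(is.na(pct), "", as.character(pct))
  full$best <- best
  full$trees[[1L]] <- best
  full$bootTrees <- reps
  full$B <- B
  full
}
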