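# Joint optimisation of branch lengths, gamma shape and invariant proportion
# on a fixed topology: L-BFGS-B over log branch lengths alternated with
# Brent line searches for the mixture parameters.

.BL_MIN <- 1e-6
.BL_MAX <- 10
.ALPHA_MIN <- 0.02
.ALPHA_MAX <- 100
.PINV_MAX <- 0.99

#' Fit the Mk(+G)(+I) model on a fixed topology
#'
#' Jointly optimises all branch lengths (bounded quasi-Newton search on the
#' log scale), the gamma shape (when `gamma = TRUE`) and the invariant
#' proportion (when `invariant = TRUE`, both by Brent line searches),
#' alternating until the relative log-likelihood improvement falls below
#' `tol` (default `1e-8`).  The optimisation is deterministic: no randomness
#' is involved.  Two fixed starting points are tried — branch lengths from
#' parsimony change counts scaled by the number of characters, and a uniform
#' 0.1 — and the better optimum is returned, guarding against local optima
#' of the branch-length surface.
#'
#' Branch lengths are bounded to `[1e-6, 10]` and alpha to `[0.02, 100]` to
#' keep the optimiser away from singular limits.  A matrix whose characters
#' are all constant carries no signal: branch lengths are then driven to the
#' lower bound and a warning is issued.
#'
#' @param tree `phylo` topology (branch lengths, if present, are ignored).
#' @param x a [TaxonAreaMatrix-class].
#' @param gamma fit discrete-gamma rate heterogeneity?
#' @param invariant fit an invariant-character proportion (+I)?
#' @param nCategories gamma category count.
#' @param control list of optional knobs: `tol` (relative lnL convergence,
#'   default `1e-8`), `maxSweeps` (outer alternation cap, default 25),
#'   `brentTol` (line-search tolerance, default `1e-7`), `lbfgsMaxit`,
#'   `factr` (inner L-BFGS-B settings), `startAlpha` (default 1).
#' @return object of class `mkFit`: list with `logLik`, `siteLogLik`, `tree`
#'   (fitted branch lengths), `alpha`, `pInvariant`, `model`, `iterations`.
#' @seealso [mkLogLik()]
#' @export
mkFit <- function(tree, x, gamma = TRUE, invariant = FALSE, nCategories = 4L,
                  control = list()) {
  stopifnot(inherits(tree, "phylo"), methods::is(x, "TaxonAreaMatrix"))
  .checkTipsMatch(tree, x)
  ctl <- modifyList(list(tol = 1e-8, maxSweeps = 25L, brentTol = 1e-7,
                         lbfgsMaxit = 200L, factr = 1e4, startAlpha = 1),
                    control)
  m <- presence(x)
  if (ncol(m) < 1L) stop("need at least one character to fit the model")
  # canonical representation (rooted at the lexicographically first tip) so
  # the fit depends only on the unrooted topology, not on how it was encoded
  if (length(tree$tip.label) > 2L)
    tree <- .anchorRoot(tree, sort(tree$tip.label)[1L])
  po <- ape::reorder.phylo(tree, "postorder")
  nE <- nrow(po$edge)

  allConstant <- all(apply(m, 2L, function(col) length(unique(col)) == 1L))
  if (allConstant)
    warning("all characters are constant: no signal, branch lengths driven to the lower bound")

  # two deterministic starts (parsimony-scaled and uniform) guard against
  # local optima of the branch-length surface
  pe <- .parsimonyEdgeChanges(po, m)
  starts <- list(pmin(pmax((pe$changes + 0.5) / ncol(m), .BL_MIN), .BL_MAX),
                 rep(0.1, nE))

  cp <- .compressPatterns(m[po$tip.label, , drop = FALSE])
  alpha <- if (gamma) ctl$startAlpha else NA_real_
  pinv <- 0

  pat <- cp$pat; storage.mode(pat) <- "integer"
  curModel <- function() mkModel(gammaShape = if (gamma) alpha else NULL,
                                 nCategories = nCategories, pInvariant = pinv)
  objective <- function()
    sum(cp$weights * log(.siteLikInternal(po, pat, curModel())))
  likGrad <- function() {
    rc <- .rateClasses(curModel())
    .mkLikGradC(po$edge, po$edge.length, length(po$tip.label), pat,
                cp$weights, rc$rates, rc$weights)
  }
  runFrom <- function(el0) {
  po$edge.length <<- el0
  alpha <<- if (gamma) ctl$startAlpha else NA_real_
  pinv <<- 0
  cur <- objective()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    prev <- cur
    # joint branch-length update: L-BFGS-B on the log scale with the
    # analytic gradient (one evaluation serves both fn and gr)
    elPrev <- po$edge.length
    cache <- list(par = NULL, val = NULL, grad = NULL)
    evalAt <- function(lb) {
      if (!identical(lb, cache$par)) {
        po$edge.length <<- exp(lb)
        lg <- likGrad()
        cache <<- list(par = lb, val = lg$logLik,
                       grad = lg$gradient * exp(lb))
      }
      cache
    }
    negll <- function(lb) -evalAt(lb)$val
    neggr <- function(lb) -evalAt(lb)$grad
    opt <- stats::optim(log(po$edge.length), negll, neggr,
                        method = "L-BFGS-B",
                        lower = log(.BL_MIN), upper = log(.BL_MAX),
                        control = list(maxit = ctl$lbfgsMaxit,
                                       factr = ctl$factr))
    # state lives in the enclosing frame (shared with objective/likGrad):
    # every write below must be a superassignment
    if (-opt$value >= cur) { po$edge.length <<- exp(opt$par); cur <- -opt$value }
    else po$edge.length <<- elPrev
    if (gamma) {
      a0 <- alpha
      g <- function(la) { alpha <<- exp(la); objective() }
      og <- stats::optimize(g, log(c(.ALPHA_MIN, .ALPHA_MAX)), maximum = TRUE,
                            tol = ctl$brentTol)
      if (og$objective >= cur) { alpha <<- exp(og$maximum); cur <- og$objective }
      else alpha <<- a0
    }
    if (invariant) {
      p0 <- pinv
      h <- function(p) { pinv <<- p; objective() }
      oh <- stats::optimize(h, c(0, .PINV_MAX), maximum = TRUE,
                            tol = ctl$brentTol)
      if (oh$objective >= cur) { pinv <<- oh$maximum; cur <- oh$objective }
      else pinv <<- p0
    }
    if (iter >= ctl$maxSweeps || (cur - prev) <= ctl$tol * abs(prev)) break
  }
  list(logLik = cur, el = po$edge.length, alpha = alpha, pinv = pinv,
       iterations = iter)
  }

  fits <- lapply(starts, runFrom)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "logLik"))]]
  po$edge.length <- best$el
  alpha <- best$alpha
  pinv <- best$pinv
  iter <- best$iterations

  model <- mkModel(gammaShape = if (gamma) alpha else NULL,
                   nCategories = nCategories, pInvariant = pinv)
  sl <- log(.siteLikInternal(po, cp$pat, model))[cp$index]
  names(sl) <- speciesNames(x)
  structure(list(logLik = sum(sl), siteLogLik = sl, tree = po,
                 alpha = alpha, pInvariant = pinv, model = model,
                 iterations = iter),
            class = "mkFit")
}

#' @export
print.mkFit <- function(x, ...) {
  cat(sprintf("Mk fit: lnL = %.6f  (-lnL = %.6f)\n", x$logLik, -x$logLik))
  if (!is.na(x$alpha)) cat(sprintf("  gamma shape alpha = %.4f\n", x$alpha))
  if (x$pInvariant > 0) cat(sprintf("  p(invariant) = %.4f\n", x$pInvariant))
  cat(sprintf("  tree length = %.4f over %d edges (%d sweeps)\n",
              sum(x$tree$edge.length), nrow(x$tree$edge), x$iterations))
  invisible(x)
}
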