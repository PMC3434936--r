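# Stochastic character mapping: joint ancestral-state sampling from the
# pruning posterior, plus endpoint-conditioned path sampling of the binary
# symmetric CTMC along each branch.

# conditional (downward) partial likelihoods for one character at one rate;
# returns list(po, L = (nodes x 2) matrix, rate)
.charPartials <- function(tree, states, rate) {
  po <- ape::reorder.phylo(tree, "postorder")
  nt <- length(po$tip.label)
  nn <- nt + po$Nnode
  if (!is.null(names(states))) states <- states[po$tip.label]
  L <- matrix(NA_real_, nn, 2L)
  L[seq_len(nt), ] <- cbind(states == 0, states == 1)
  touched <- rep(FALSE, nn)
  E <- po$edge
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    ee <- exp(-2 * rate * po$edge.length[e])
    ps <- (1 + ee) / 2; pd <- (1 - ee) / 2
    msg <- c(ps * L[ch, 1L] + pd * L[ch, 2L],
             pd * L[ch, 1L] + ps * L[ch, 2L])
    if (touched[p]) L[p, ] <- L[p, ] * msg
    else { L[p, ] <- msg; touched[p] <- TRUE }
  }
  list(po = po, L = L, rate = rate)
}

#' Sample joint ancestral states for one character
#'
#' Draws one joint sample of all node states from their posterior under the
#' symmetric binary Mk chain: the root state from its conditional posterior
#' (pruning partials times the uniform root prior), then each descendant
#' top-down from transition probability times subtree partial.  Marginal
#' frequencies of repeated samples converge to the pruning-based marginal
#' posteriors.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param states named 0/1 tip vector (one matrix column).
#' @param rate rate multiplier for this character (see [characterRate()]).
#' @return integer vector of sampled states for nodes `1..Ntip+Nnode` (tips
#'   keep their observed states).
#' @export
sampleAncestralStates <- function(tree, states, rate = 1) {
  cp <- .charPartials(tree, states, rate)
  .sampleStatesFromPartials(cp)
}

.sampleStatesFromPartials <- function(cp) {
  po <- cp$po; L <- cp$L
  nt <- length(po$tip.label)
  nn <- nt + po$Nnode
  E <- po$edge
  root <- E[nrow(E), 1L]
  out <- integer(nn)
  out[seq_len(nt)] <- as.integer(L[seq_len(nt), 2L] > 0)
  pr <- 0.5 * L[root, ]
  out[root] <- as.integer(stats::runif(1) < pr[2L] / sum(pr))
  for (e in rev(seq_len(nrow(E)))) {          # preorder
    p <- E[e, 1L]; v <- E[e, 2L]
    if (v <= nt) next
    ee <- exp(-2 * cp$rate * po$edge.length[e])
    ps <- (1 + ee) / 2; pd <- (1 - ee) / 2
    w1 <- (if (out[p] == 1L) ps else pd) * L[v, 2L]
    w0 <- (if (out[p] == 0L) ps else pd) * L[v, 1L]
    out[v] <- as.integer(stats::runif(1) < w1 / (w0 + w1))
  }
  out
}

#' Endpoint-conditioned path of the binary symmetric chain on one branch
#'
#' Samples a full state path conditioned on both endpoint states, by drawing
#' the number of state flips from a Poisson(`rate * t`) distribution
#' restricted to the parity of the endpoint disagreement (for the symmetric
#' two-state chain with dominating rate equal to the leaving rate, every
#' auxiliary event is a real flip, so this is the exact conditional law),
#' then placing the flip times as uniform order statistics.
#'
#' @param stateStart,stateEnd endpoint states in `{0, 1}`.
#' @param t branch length `>= 0`.
#' @param rate positive rate multiplier.
#' @return `data.frame(state, duration)`, rootward segment first; durations
#'   sum to `t` and adjacent states differ.
#' @export
sampleBranchHistory <- function(stateStart, stateEnd, t, rate = 1) {
  stopifnot(stateStart %in% c(0, 1), stateEnd %in% c(0, 1), t >= 0, rate > 0)
  parity <- as.integer(stateStart != stateEnd)
  if (t == 0) {
    if (parity == 1L) stop("impossible path: t = 0 with unequal endpoints")
    return(data.frame(state = stateStart, duration = 0))
  }
  nflips <- .rcondPoisson(rate * t, parity)
  if (nflips == 0L)
    return(data.frame(state = stateStart, duration = t))
  times <- sort(stats::runif(nflips)) * t
  bounds <- c(0, times, t)
  states <- (stateStart + (seq_len(nflips + 1L) - 1L)) %% 2
  data.frame(state = states, duration = diff(bounds))
}

# Poisson(lambda) conditioned on k %% 2 == parity, by inverse CDF over the
# restricted support
.rcondPoisson <- function(lambda, parity) {
  norm <- if (parity == 0L) (1 + exp(-2 * lambda)) / 2
          else (1 - exp(-2 * lambda)) / 2
  if (norm <= 0) return(as.integer(parity))   # lambda ~ 0, forced minimum
  u <- stats::runif(1) * norm
  k <- as.integer(parity)
  p <- stats::dpois(k, lambda)
  acc <- p
  while (acc < u && k < 10000L) {
    p <- p * lambda^2 / ((k + 1) * (k + 2))
    k <- k + 2L
    acc <- acc + p
  }
  k
}

#' Posterior-mean rate of one character under a fitted Mk model
#'
#' The default per-character rate used for stochastic mapping: the
#' posterior mean of the rate-class multiplier given the character's data,
#' mixing the discrete-gamma classes (and the zero-rate invariant class when
#' present) by their conditional likelihoods.
#'
#' @param tree `phylo` with branch lengths.
#' @param states named 0/1 tip vector.
#' @param model an [MkModel-class].
#' @return a single positive rate.
#' @export
characterRate <- function(tree, states, model) {
  rc <- .rateClasses(model)
  if (length(rc$rates) == 1L) return(rc$rates)
  lik <- vapply(rc$rates, function(r) {
    cp <- .charPartials(tree, states, max(r, 0))
    root <- cp$po$edge[nrow(cp$po$edge), 1L]
    0.5 * sum(cp$L[root, ])
  }, numeric(1))
  w <- rc$weights * lik
  sum(w * rc$rates) / sum(w)
}

#' Stochastic character mapping of one species on an area tree
#'
#' Draws `nSamples` independent full histories of one species (character):
#' joint node states from the posterior, then endpoint-conditioned paths
#' along every branch; summarises them as per-node presence posteriors,
#' per-branch expected occupancy of state 1, and per-branch expected counts
#' of gains (0 to 1) and losses (1 to 0).
#'
#' @param tree rooted `phylo` with branch lengths (typically the fitted tree
#'   of [mkFit()] or [treeSearch()]).
#' @param x a [TaxonAreaMatrix-class].
#' @param species species (column) name to map.
#' @param model fitted [MkModel-class] used for the per-character rate.
#' @param nSamples number of sampled histories.
#' @param seed optional integer seed.
#' @param uniformRate if `TRUE` use rate 1 instead of the posterior-mean
#'   character rate.
#' @param keepHistories return the individual histories (lists of per-branch
#'   segment tables) as well as the summary?
#' @return object of class `mapSummary`: list with `species`, `rate`,
#'   `nodePosterior` (presence probability per node), `expectedOccupancy`,
#'   `expectedGains`, `expectedLosses` (per edge of `tree`), `nSamples`,
#'   `seed`, `tree`, and (optionally) `histories`.
#' @export
mapCharacter <- function(tree, x, species, model = mkModel(),
                         nSamples = 1000L, seed = NULL,
                         uniformRate = FALSE, keepHistories = FALSE) {
  stopifnot(methods::is(x, "TaxonAreaMatrix"))
  if (!species %in% speciesNames(x))
    stop("unknown species '", species, "'")
  .checkTipsMatch(tree, x)
  if (!is.null(seed)) set.seed(seed)
  states <- presence(x)[, species]
  rate <- if (uniformRate) 1 else characterRate(tree, states, model)
  rate <- max(rate, 1e-12)
  cp <- .charPartials(tree, states, rate)
  po <- cp$po
  E <- po$edge
  nE <- nrow(E)
  nn <- length(po$tip.label) + po$Nnode
  nodeHits <- numeric(nn)
  occ <- numeric(nE); gains <- numeric(nE); losses <- numeric(nE)
  histories <- if (keepHistories) vector("list", nSamples) else NULL
  for (s in seq_len(nSamples)) {
    st <- .sampleStatesFromPartials(cp)
    nodeHits <- nodeHits + st
    segs <- vector("list", nE)
    for (e in seq_len(nE)) {
      seg <- sampleBranchHistory(st[E[e, 1L]], st[E[e, 2L]],
                                 po$edge.length[e], rate)
      occ[e] <- occ[e] + sum(seg$duration[seg$state == 1])
      if (nrow(seg) > 1L) {
        d <- diff(seg$state)
        gains[e] <- gains[e] + sum(d == 1)
        losses[e] <- losses[e] + sum(d == -1)
      }
      if (keepHistories) segs[[e]] <- seg
    }
    if (keepHistories)
      histories[[s]] <- list(nodeStates = st, segments = segs)
  }
  structure(list(species = species, rate = rate,
                 nodePosterior = nodeHits / nSamples,
                 expectedOccupancy = occ / nSamples,
                 expectedGains = gains / nSamples,
                 expectedLosses = losses / nSamples,
                 nSamples = nSamples, seed = seed, tree = po,
                 histories = histories),
            class = "mapSummary")
}

#' @export
print.mapSummary <- function(x, ...) {
  cat(sprintf(
    "Stochastic map of '%s': %d samples, rate %.4f\n", x$species,
    x$nSamples, x$rate))
  cat(sprintf("  expected gains %.3f, losses %.3f over the tree\n",
              sum(x$expectedGains), sum(x$expectedLosses)))
  invisible(x)
}

#' Marginal ancestral presence posteriors (pruning oracle)
#'
#' Exact per-node marginal posterior probability of presence for one
#' character, computed from downward and upward pruning partials.  Used to
#' validate the sampled frequencies of [mapCharacter()].
#'
#' @inheritParams sampleAncestralStates
#' @return numeric vector of P(state 1) per node `1..Ntip+Nnode`.
#' @export
marginalPosterior <- function(tree, states, rate = 1) {
  cp <- .charPartials(tree, states, rate)
  po <- cp$po; L <- cp$L
  nt <- length(po$tip.label)
  nn <- nt + po$Nnode
  E <- po$edge
  root <- E[nrow(E), 1L]
  up <- matrix(NA_real_, nn, 2L)            # partial above each node
  up[root, ] <- c(0.5, 0.5)
  for (e in rev(seq_len(nrow(E)))) {
    p <- E[e, 1L]; v <- E[e, 2L]
    sibs <- setdiff(E[E[, 1L] == p, 2L], v)
    msg <- up[p, ]
    for (b in sibs) {
      eb <- which(E[, 2L] == b)
      ee <- exp(-2 * cp$rate * po$edge.length[eb])
      ps <- (1 + ee) / 2; pd <- (1 - ee) / 2
      mb <- c(ps * L[b, 1L] + pd * L[b, 2L], pd * L[b, 1L] + ps * L[b, 2L])
      msg <- msg * mb
    }
    ee <- exp(-2 * cp$rate * po$edge.length[e])
    ps <- (1 + ee) / 2; pd <- (1 - ee) / 2
    up[v, ] <- c(ps * msg[1L] + pd * msg[2L], pd * msg[1L] + ps * msg[2L])
  }
  post <- up * L
  post[, 2L] / rowSums(post)
}
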