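# Independent oracles used across the suite.  These deliberately avoid the
# package's pruning/search code paths: likelihoods by explicit summation over
# ancestral-state assignments, parsimony by exhaustive labelling/topology
# enumeration.

# log-likelihood by brute-force summation over all internal-state
# assignments (trees with <= 6 tips)
bruteLogLik <- function(tree, m, rates = 1, weights = 1) {
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  nt <- length(po$tip.label)
  nn <- nt + po$Nnode
  ints <- (nt + 1L):nn
  total <- 0
  for (ch in seq_len(ncol(m))) {
    tipStates <- m[po$tip.label, ch]
    lik <- 0
    for (k in seq_along(rates)) {
      r <- rates[k]
      likk <- 0
      for (assign in 0:(2^length(ints) - 1L)) {
        st <- integer(nn)
        st[seq_len(nt)] <- tipStates
        st[ints] <- as.integer(intToBits(assign))[seq_along(ints)]
        p <- 0.5
        for (e in seq_len(nrow(E))) {
          ee <- exp(-2 * r * po$edge.length[e])
          same <- st[E[e, 1L]] == st[E[e, 2L]]
          p <- p * (if (same) (1 + ee) / 2 else (1 - ee) / 2)
        }
        likk <- likk + p
      }
      lik <- lik + weights[k] * likk
    }
    total <- total + log(lik)
  }
  total
}

# minimum-change labellings by exhaustive enumeration; returns per-node MP
# state sets and the minimum length
bruteMPSets <- function(tree, states) {
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  nt <- length(po$tip.label)
  nn <- nt + po$Nnode
  ints <- (nt + 1L):nn
  st0 <- states[po$tip.label]
  best <- Inf
  sets <- replicate(nn, integer(0), simplify = FALSE)
  for (assign in 0:(2^length(ints) - 1L)) {
    st <- integer(nn)
    st[seq_len(nt)] <- st0
    st[ints] <- as.integer(intToBits(assign))[seq_along(ints)]
    len <- sum(st[E[, 1L]] != st[E[, 2L]])
    if (len < best) {
      best <- len
      sets <- replicate(nn, integer(0), simplify = FALSE)
    }
    if (len == best)
      for (v in seq_len(nn)) sets[[v]] <- union(sets[[v]], st[v])
  }
  list(sets = lapply(sets, sort), length = best)
}

# random binary matrix on a random tree, for property tests
randomInstance <- function(ntip, nchar, blrange = c(0.05, 1)) {
  tr <- ape::rtree(ntip)
  tr$edge.length <- stats::runif(nrow(tr$edge), blrange[1], blrange[2])
  m <- matrix(stats::rbinom(ntip * nchar, 1, 0.5), ntip, nchar,
              dimnames = list(tr$tip.label, sprintf("s%d", seq_len(nchar))))
  list(tree = tr, m = m, x = taxonAreaMatrix(m))
}

# all unrooted topologies on a tip set (phangorn enumeration utility)
allTopologies <- function(tips) phangorn::allTrees(length(tips), tip.label = tips)
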