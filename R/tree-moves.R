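# Topology rearrangements for the heuristic search.  Search trees are kept
# rooted at a fixed "anchor" tip (root has two children: the anchor and the
# rest); pruning any clade not containing the anchor and regrafting it on any
# remaining edge then spans the full unrooted SPR neighbourhood, and NNI is
# the subset of swaps across internal edges.

# parent/children arrays from a rooted binary phylo
.treeLists <- function(phy) {
  nn <- length(phy$tip.label) + phy$Nnode
  par <- integer(nn)
  kids <- vector("list", nn)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    par[ch] <- p
    kids[[p]] <- c(kids[[p]], ch)
  }
  list(par = par, kids = kids, root = length(phy$tip.label) + 1L,
       ntip = length(phy$tip.label), labels = phy$tip.label)
}

.listsNewick <- function(tl) {
  rec <- function(v) {
    if (v <= tl$ntip) .nexusQuote(tl$labels[v])
    else paste0("(", paste(vapply(tl$kids[[v]], rec, character(1)),
                           collapse = ","), ")")
  }
  paste0(rec(tl$root), ";")
}

.listsPhylo <- function(tl) ape::read.tree(text = .listsNewick(tl))

# root an arbitrary (possibly unrooted) topology at the anchor tip
.anchorRoot <- function(phy, anchor) {
  phy <- ape::unroot(phy)
  ape::root(phy, outgroup = anchor, resolve.root = TRUE)
}

# canonical key of the unrooted topology: sorted nontrivial splits, each
# canonicalised to the side not containing the lexicographically first tip
.topoKey <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  nt <- length(po$tip.label)
  nn <- nt + po$Nnode
  allTips <- sort(po$tip.label)
  ref <- allTips[1L]
  below <- vector("list", nn)
  for (v in seq_len(nt)) below[[v]] <- po$tip.label[v]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  splits <- vapply((nt + 1L):nn, function(v) {
    s <- below[[v]]
    if (ref %in% s) s <- setdiff(allTips, s)
    s <- sort(s)
    if (length(s) <= 1L || length(s) >= nt - 1L) NA_character_
    else paste(s, collapse = "|")
  }, character(1))
  paste(sort(unique(stats::na.omit(splits))), collapse = ";")
}

# descendants of v (inclusive) in a .treeLists structure
.descendants <- function(tl, v) {
  out <- integer(0); stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, x)
    stack <- c(stack, tl$kids[[x]])
  }
  out
}

# all NNI rearrangements of the unrooted topology, as anchor-rooted phylo
# objects, deduplicated by topology
.nniNeighbors <- function(phy) {
  tl <- .treeLists(phy)
  res <- list(); keys <- character(0)
  for (ch in seq_along(tl$par)) {
    p <- tl$par[ch]
    if (ch <= tl$ntip || p == 0L || p == tl$root) next
    # edge p-ch joins two internal nodes: two swaps of a child of ch with
    # ch's sibling
    sib <- setdiff(tl$kids[[p]], ch)
    for (gc in tl$kids[[ch]]) {
      tl2 <- tl
      tl2$kids[[p]] <- c(setdiff(tl2$kids[[p]], sib), gc)
      tl2$kids[[ch]] <- c(setdiff(tl2$kids[[ch]], gc), sib)
      tl2$par[sib] <- ch; tl2$par[gc] <- p
      nb <- .listsPhylo(tl2)
      k <- .topoKey(nb)
      if (!k %in% keys) { keys <- c(keys, k); res <- c(res, list(nb)) }
    }
  }
  res
}

# all SPR rearrangements of the unrooted topology, deduplicated; a strict
# superset of the NNI neighbourhood.  Every split side S is pruned exactly
# once, in the rooting anchored at the first tip (sorted order) outside S,
# and regrafted on every remaining edge.
.sprNeighbors <- function(phy) {
  un <- ape::unroot(phy)
  tips <- sort(un$tip.label)
  res <- list(); keys <- .topoKey(phy)   # seed with self so it is excluded
  for (anchor in tips) {
    rphy <- .anchorRoot(un, anchor)
    tl <- .treeLists(rphy)
    for (x in seq_along(tl$par)) {
      p <- tl$par[x]
      if (x == tl$root || p == 0L || p == tl$root) next
      inX <- .descendants(tl, x)
      inTips <- tl$labels[inX[inX <= tl$ntip]]
      if (setdiff(tips, inTips)[1L] != anchor) next  # canonical rooting only
      g <- tl$par[p]
      sib <- setdiff(tl$kids[[p]], x)
      basePar <- tl$par; baseKids <- tl$kids
      baseKids[[g]] <- c(setdiff(baseKids[[g]], p), sib)
      basePar[sib] <- g
      baseKids[[p]] <- integer(0)
      remaining <- setdiff(seq_along(tl$par), c(inX, p, tl$root))
      for (b in remaining) {
        tl2 <- tl
        tl2$par <- basePar; tl2$kids <- baseKids
        gb <- tl2$par[b]
        # re-use the retired node p as the new attachment on edge gb-b
        tl2$kids[[gb]] <- c(setdiff(tl2$kids[[gb]], b), p)
        tl2$kids[[p]] <- c(b, x)
        tl2$par[p] <- gb; tl2$par[b] <- p; tl2$par[x] <- p
        nb <- .listsPhylo(tl2)
        k <- .topoKey(nb)
        if (!k %in% keys) { keys <- c(keys, k); res <- c(res, list(nb)) }
      }
    }
  }
  res
}

# stepwise random-addition starting tree; insertions are scored by Fitch
# parsimony on the taxa added so far
.randomAdditionTree <- function(x, order = NULL) {
  areas <- areaNames(x)
  n <- length(areas)
  stopifnot(n >= 3L)
  if (is.null(order)) order <- sample(areas)
  anchor <- order[1L]
  cur <- ape::read.tree(text = sprintf("(%s,(%s,%s));",
    .nexusQuote(order[1L]), .nexusQuote(order[2L]), .nexusQuote(order[3L])))
  if (n == 3L) return(cur)
  for (i in 4L:n) {
    taxon <- order[i]
    sub <- x[order[seq_len(i)], ]
    tl <- .treeLists(cur)
    best <- NULL; bestScore <- Inf
    for (ch in seq_along(tl$par)) {
      if (ch == tl$root) next
      p <- tl$par[ch]
      tl2 <- tl
      newNode <- length(tl2$par) + 1L
      newTip <- length(tl2$par) + 2L   # ids only matter for surgery
      tl2$par <- c(tl2$par, 0L, 0L)
      tl2$kids <- c(tl2$kids, vector("list", 2L))
      tl2$kids[[p]] <- c(setdiff(tl2$kids[[p]], ch), newNode)
      tl2$kids[[newNode]] <- c(ch, newTip)
      tl2$par[newNode] <- p; tl2$par[ch] <- newNode; tl2$par[newTip] <- newNode
      tl2$labels <- c(tl2$labels, taxon)
      # newTip id exceeds ntip numbering; emit via labels lookup
      cand <- .insertionPhylo(tl2, newTip)
      sc <- .fitchLengthOnly(cand, sub)
      if (sc < bestScore) { bestScore <- sc; best <- cand }
    }
    cur <- best
  }
  .anchorRoot(cur, areas[1L])
}

# newick emission for the insertion structure, where tip ids are those nodes
# with no children and a label
.insertionPhylo <- function(tl, newTip) {
  rec <- function(v) {
    if (length(tl$kids[[v]]) == 0L) {
      lab <- if (v <= tl$ntip) tl$labels[v] else tl$labels[length(tl$labels)]
      .nexusQuote(lab)
    } else paste0("(", paste(vapply(tl$kids[[v]], rec, character(1)),
                             collapse = ","), ")")
  }
  ape::read.tree(text = paste0(rec(tl$root), ";"))
}
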