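#' Append an all-zero artificial outgroup area
#'
#' Adds one extra area row containing no species.  Rooting area trees on this
#' hypothetical ancestral area is the standard device of the analysis: under
#' parsimony the row is cost-free, while under the Mk likelihood it anchors
#' the tree on a state of complete absence.
#'
#' @param x a [TaxonAreaMatrix-class].
#' @param name name for the artificial area (must not collide with an
#'   existing area).
#' @return the matrix with one additional all-zero row; original rows
#'   unchanged.
#' @export
addAllZeroOutgroup <- function(x, name = "ROOT") {
  stopifnot(methods::is(x, "TaxonAreaMatrix"))
  if (name %in% areaNames(x))
    stop("outgroup name collision: area '", name, "' already exists")
  m <- presence(x)
  m2 <- rbind(m, matrix(0L, 1L, ncol(m), dimnames = list(name, colnames(m))))
  taxonAreaMatrix(m2, provenance = provenance(x))
}

#' Drop an area (typically the artificial outgroup) from a tree
#'
#' @param tree a `phylo`.
#' @param name tip label to remove.
#' @return the pruned `phylo`.
#' @export
dropOutgroup <- function(tree, name = "ROOT") {
  if (!name %in% tree$tip.label)
    stop("tip '", name, "' not in tree")
  ape::drop.tip(tree, name)
}

#' Lundberg rooting on the least-occupied area
#'
#' Roots an unrooted area tree a posteriori on the terminal branch of the
#' area with the fewest species presences (smallest row sum), placing the
#' root at the midpoint of that branch.  The unrooted topology is unchanged.
#' A tie for the minimum is an error: the choice must then be made
#' explicitly via `area`.
#'
#' @param tree unrooted `phylo` whose tips are areas of `x`.
#' @param x the [TaxonAreaMatrix-class] supplying occurrence counts.
#' @param area optional explicit area to root on (overrides the minimum rule,
#'   e.g. to break a tie).
#' @return rooted `phylo`.
#' @export
lundbergRoot <- function(tree, x, area = NULL) {
  stopifnot(inherits(tree, "phylo"), methods::is(x, "TaxonAreaMatrix"))
  if (!all(tree$tip.label %in% areaNames(x)))
    stop("tree tips not all present in matrix areas: ",
         paste(setdiff(tree$tip.label, areaNames(x)), collapse = ", "))
  if (is.null(area)) {
    occ <- rowSums(presence(x))[tree$tip.label]
    mn <- min(occ)
    ties <- names(occ)[occ == mn]
    if (length(ties) > 1L)
      stop("tie for minimum occurrence between areas ",
           paste(ties, collapse = ", "),
           "; pass `area` to choose the outgroup explicitly")
    area <- ties
  }
  if (!area %in% tree$tip.label) stop("area '", area, "' not in tree")
  rooted <- ape::root(ape::unroot(tree), outgroup = area, resolve.root = TRUE)
  if (!is.null(rooted$edge.length)) {
    # place the root at the midpoint of the outgroup's terminal branch
    nt <- length(rooted$tip.label)
    rootNode <- nt + 1L
    tipIdx <- match(area, rooted$tip.label)
    eTip <- which(rooted$edge[, 1L] == rootNode & rooted$edge[, 2L] == tipIdx)
    eOther <- setdiff(which(rooted$edge[, 1L] == rootNode), eTip)
    total <- sum(rooted$edge.length[c(eTip, eOther)])
    pendant <- tree$edge.length[which(
      tree$edge[, 2L] == match(area, tree$tip.label))]
    rooted$edge.length[eTip] <- pendant / 2
    rooted$edge.length[eOther] <- total - pendant / 2
  }
  rooted
}

#' Majority-rule consensus with percentage supports
#'
#' Wraps [ape::consensus()] and annotates every retained internal node with
#' the percentage of input trees containing its bipartition
#' (via [ape::prop.clades()]).
#'
#' @param trees list (or `multiPhylo`) of trees on an identical tip set.
#' @param threshold minimum bipartition frequency to retain, in `[0.5, 1]`.
#' @return consensus `phylo`; `$node.label` holds percentage supports
#'   (root label empty).
#' @export
majorityConsensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1L, threshold >= 0.5, threshold <= 1)
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(tipsets, identical, logical(1), y = tipsets[[1L]])))
    stop("trees have mismatched tip sets")
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = threshold, rooted = FALSE, check.labels = TRUE)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  pct <- round(100 * counts / length(trees), 1)
  cons$node.label <- ifelse(is.na(pct), "", as.character(pct))
  cons
}

#' Robinson-Foulds distance between two area trees
#'
#' Symmetric-difference count of nontrivial bipartitions, via
#' [phangorn::RF.dist()].  With `unrooted = TRUE` (the default) both trees
#' are unrooted first, so any rooting is ignored.
#'
#' @param t1,t2 `phylo` objects on the same tip set.
#' @param unrooted compare unrooted topologies (default) or rooted clades.
#' @return non-negative integer.
#' @export
rfDistance <- function(t1, t2, unrooted = TRUE) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have mismatched tip sets")
  if (unrooted) { t1 <- ape::unroot(t1); t2 <- ape::unroot(t2) }
  as.integer(phangorn::RF.dist(t1, t2, rooted = !unrooted))
}
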