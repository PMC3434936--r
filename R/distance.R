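#' Pairwise area distances from a taxon-area matrix
#'
#' `hamming` is the proportion of species whose presence state differs
#' between two areas (treating 0 and 1 symmetrically, consistent with the
#' symmetric Mk model); `jaccard` is one minus the ratio of shared to
#' combined presences (defined as 0 when both areas are empty).
#'
#' @param x a [TaxonAreaMatrix-class] with at least two areas.
#' @param metric `"hamming"` (default) or `"jaccard"`.
#' @return a symmetric `dist`-convertible matrix with entries in `[0, 1]`,
#'   zero diagonal and a `"metric"` attribute.
#' @export
areaDistance <- function(x, metric = c("hamming", "jaccard")) {
  stopifnot(methods::is(x, "TaxonAreaMatrix"))
  metric <- match.arg(metric)
  m <- presence(x)
  if (nrow(m) < 2L) stop("need at least two areas")
  if (metric == "hamming") {
    if (ncol(m) == 0L) d <- matrix(0, nrow(m), nrow(m))
    else {
      shared11 <- tcrossprod(m)
      shared00 <- tcrossprod(1 - m)
      d <- 1 - (shared11 + shared00) / ncol(m)
    }
  } else {
    inter <- tcrossprod(m)
    sums <- rowSums(m)
    union <- outer(sums, sums, "+") - inter
    d <- ifelse(union == 0, 0, 1 - inter / pmax(union, 1))
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "metric") <- metric
  d
}

#' UPGMA dendrogram of areas
#'
#' Average-linkage agglomerative clustering of the area distance matrix.
#' Areas are canonicalised to lexicographic order before clustering so that
#' the result is invariant under permutation of the input rows; heights are
#' halved merge distances, making the output ultrametric (all root-to-tip
#' paths equal).
#'
#' @param d symmetric distance matrix (e.g. from [areaDistance()]) or a
#'   `dist` object.
#' @return an ultrametric `phylo` dendrogram.
#' @export
upgmaTree <- function(d) {
  dm <- as.matrix(d)
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  ape::as.phylo(hc)
}
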