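#' Construct a taxon-area matrix
#'
#' Builds a validated [TaxonAreaMatrix-class] from a 0/1 matrix whose rows are
#' areas and columns are species.
#'
#' @param cells numeric or integer matrix of 0/1 values, areas in rows and
#'   species in columns.  Dimnames may be supplied either on the matrix or
#'   through `areas` / `species`.
#' @param areas,species optional character vectors of row/column names,
#'   overriding any dimnames on `cells`.
#' @param provenance free-text source tag stored with the object.
#' @param x a `TaxonAreaMatrix`.
#'
#' @return A `TaxonAreaMatrix`.  `areaNames()` and `speciesNames()` return the
#'   row and column names, `presence()` the underlying integer matrix and
#'   `provenance()` the source tag.
#'
#' @examples
#' m <- taxonAreaMatrix(rbind(A = c(1, 0), B = c(0, 1)),
#'                      species = c("sp1", "sp2"))
#' areaNames(m)
#' presence(m)
#' @export
taxonAreaMatrix <- function(cells, areas = NULL, species = NULL,
                            provenance = "in-memory") {
  cells <- as.matrix(cells)
  if (!is.null(areas)) rownames(cells) <- areas
  if (!is.null(species)) colnames(cells) <- species
  if (is.null(colnames(cells)) && ncol(cells) == 0L)
    colnames(cells) <- character(0)
  storage.mode(cells) <- "integer"
  methods::new("TaxonAreaMatrix", cells = cells,
               provenance = as.character(provenance)[1L])
}

#' @rdname taxonAreaMatrix
#' @export
setMethod("areaNames", "TaxonAreaMatrix", function(x) rownames(x@cells))

#' @rdname taxonAreaMatrix
#' @export
setMethod("speciesNames", "TaxonAreaMatrix", function(x) colnames(x@cells))

#' @rdname taxonAreaMatrix
#' @export
setMethod("presence", "TaxonAreaMatrix", function(x) x@cells)

#' @rdname taxonAreaMatrix
#' @export
setMethod("provenance", "TaxonAreaMatrix", function(x) x@provenance)

#' @export
setMethod("dim", "TaxonAreaMatrix", function(x) dim(x@cells))

#' Subset a taxon-area matrix
#'
#' Standard `[` subsetting by area and/or species, returning a validated
#' `TaxonAreaMatrix` (dimensions are never dropped).
#'
#' @param x a `TaxonAreaMatrix`.
#' @param i,j area and species indices (numeric, logical or names).
#' @param ... ignored.
#' @param drop ignored; always `FALSE`.
#' @export
setMethod("[", "TaxonAreaMatrix", function(x, i, j, ..., drop = FALSE) {
  m <- x@cells
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  methods::initialize(x, cells = m)
})

setMethod("show", "TaxonAreaMatrix", function(object) {
  m <- object@cells
  cat(sprintf("TaxonAreaMatrix: %d areas x %d species\n", nrow(m), ncol(m)))
  if (length(m)) {
    occ <- rowSums(m)
    cat(sprintf("  occupancy per area: %d-%d (mean %.1f)\n",
                min(occ), max(occ), mean(occ)))
    cat(sprintf("  constant characters: %d all-zero, %d all-one\n",
                sum(colSums(m) == 0L), sum(colSums(m) == nrow(m))))
  }
  cat(sprintf("  provenance: %s\n", object@provenance))
  invisible(object)
})

#' @export
as.matrix.TaxonAreaMatrix <- function(x, ...) x@cells
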