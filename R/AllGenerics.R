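#' @rdname taxonAreaMatrix
#' @export
setGeneric("areaNames", function(x) standardGeneric("areaNames"))

#' @rdname taxonAreaMatrix
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname taxonAreaMatrix
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname taxonAreaMatrix
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
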