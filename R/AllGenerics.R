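# Accessors (Bioconductor style: no direct slot access in user code)

#' @export
setGeneric("evenPart", function(x) standardGeneric("evenPart"))
#' @export
setGeneric("oddParts", function(x) standardGeneric("oddParts"))
#' @export
setGeneric("amplitudeMap", function(x) standardGeneric("amplitudeMap"))
#' @export
setGeneric("phaseMap", function(x) standardGeneric("phaseMap"))
#' @export
setGeneric("orientationMap", function(x) standardGeneric("orientationMap"))
#' @export
setGeneric("edgeValues", function(x) standardGeneric("edgeValues"))
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))
#' @export
setGeneric("seedPoints", function(x) standardGeneric("seedPoints"))
#' @export
setGeneric("chainPoints", function(x) standardGeneric("chainPoints"))
#' @export
setGeneric("chainChord", function(x) standardGeneric("chainChord"))
#' @export
setGeneric("chainNormals", function(x) standardGeneric("chainNormals"))
#' @export
setGeneric("chainThickness", function(x) standardGeneric("chainThickness"))

#' Accessors for fcseg S4 containers
#'
#' Small read-only accessors returning the underlying matrices/vectors of
#' the package's S4 classes.
#'
#' @param x an fcseg S4 object
#' @return the requested component (a matrix, vector or list of matrices)
#' @name accessors
#' @aliases evenPart oddParts amplitudeMap phaseMap orientationMap edgeValues
#'   connValues seedPoints chainPoints chainChord chainNormals chainThickness
NULL

#' @rdname accessors
#' @export
setMethod("evenPart", "MonogenicResponse", function(x) x@even)
#' @rdname accessors
#' @export
setMethod("oddParts", "MonogenicResponse",
          function(x) list(odd1 = x@odd1, odd2 = x@odd2))
#' @rdname accessors
#' @export
setMethod("amplitudeMap", "PhaseMaps", function(x) x@amplitude)
#' @rdname accessors
#' @export
setMethod("phaseMap", "PhaseMaps", function(x) x@phase)
#' @rdname accessors
#' @export
setMethod("orientationMap", "PhaseMaps", function(x) x@orientation)
#' @rdname accessors
#' @export
setMethod("edgeValues", "EdgeMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("connValues", "ConnectivityMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("seedPoints", "ConnectivityMap", function(x) x@seeds)
#' @rdname accessors
#' @export
setMethod("chainPoints", "BoundaryChain", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("chainChord", "BoundaryChain", function(x) x@chord)
#' @rdname accessors
#' @export
setMethod("chainNormals", "BoundaryChain", function(x) x@normals)
#' @rdname accessors
#' @export
setMethod("chainThickness", "BoundaryChain", function(x) x@thickness)
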