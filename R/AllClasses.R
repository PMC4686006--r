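#' @import methods
NULL

#' Bandpass filter specification
#'
#' Describes the radial bandpass filter used to build the monogenic signal:
#' a Gaussian-derivative profile \eqn{B(u) = |u| \exp(-|u|^2 \sigma^2)} on a
#' frequency grid in cycles/pixel, scaled to unit peak gain. The filter is
#' DC-free by construction, which is what makes local phase contrast
#' invariant.
#'
#' @slot sigma numeric(1), filter scale; larger sigma selects lower spatial
#'   frequencies (the continuous peak sits at \eqn{|u| = 1/(\sigma\sqrt{2})}).
#' @slot kind character(1), bandpass family; only "gaussian_derivative" is
#'   implemented.
#'
#' @examples
#' bandpassSpec(27)
#' @export
setClass("BandpassSpec",
  representation(sigma = "numeric", kind = "character"),
  prototype(sigma = 27, kind = "gaussian_derivative"))

setValidity("BandpassSpec", function(object) {
  if (length(object@sigma) != 1L || !is.finite(object@sigma) || object@sigma <= 0)
    return("'sigma' must be a single positive finite number")
  if (!identical(object@kind, "gaussian_derivative"))
    return("unsupported bandpass kind: only 'gaussian_derivative' is available")
  TRUE
})

#' @param sigma filter scale (> 0)
#' @param kind bandpass family identifier
#' @rdname BandpassSpec-class
#' @export
bandpassSpec <- function(sigma, kind = "gaussian_derivative") {
  new("BandpassSpec", sigma = as.numeric(sigma), kind = kind)
}

#' Monogenic signal of an image at one scale
#'
#' Holds the even (bandpassed) response and the two odd Riesz responses of an
#' image at a single filter scale, the 2D analogue of the analytic signal.
#'
#' @slot even matrix, bandpassed image \eqn{I_b}
#' @slot odd1 matrix, first Riesz component (row-frequency axis)
#' @slot odd2 matrix, second Riesz component (column-frequency axis)
#' @slot spec the \linkS4class{BandpassSpec} used
#' @seealso [monogenicSignal()], [phaseMaps()]
#' @export
setClass("MonogenicResponse",
  representation(even = "matrix", odd1 = "matrix", odd2 = "matrix",
                 spec = "BandpassSpec"))

setValidity("MonogenicResponse", function(object) {
  d <- dim(object@even)
  if (!identical(d, dim(object@odd1)) || !identical(d, dim(object@odd2)))
    return("even/odd1/odd2 must share the same dimensions")
  TRUE
})

#' Local amplitude, phase and orientation maps
#'
#' Pointwise decomposition of a \linkS4class{MonogenicResponse}: amplitude
#' (local energy), local phase and local orientation. With the folded phase
#' convention, phase lives in \eqn{[0, \pi]}: 0 at the crest of a bright
#' structure (strong positive even response), \eqn{\pi} at the crest of a
#' dark structure, \eqn{\pi/2} on step edges.
#'
#' @slot amplitude matrix, \eqn{A \ge 0}
#' @slot phase matrix, radians
#' @slot orientation matrix, radians in \eqn{[0, \pi)}
#' @slot convention character(1), "folded" or "raw"
#' @export
setClass("PhaseMaps",
  representation(amplitude = "matrix", phase = "matrix",
                 orientation = "matrix", convention = "character"))

setValidity("PhaseMaps", function(object) {
  d <- dim(object@amplitude)
  if (!identical(d, dim(object@phase)) || !identical(d, dim(object@orientation)))
    return("amplitude/phase/orientation must share the same dimensions")
  if (any(object@amplitude < 0)) return("amplitude must be non-negative")
  TRUE
})

#' Thinned edge map
#'
#' Per-pixel edge strength in \eqn{[0, 1]} after feature asymmetry and
#' modified non-maximal suppression; drives the homogeneity affinity term.
#'
#' @slot values matrix in \eqn{[0, 1]}
#' @export
setClass("EdgeMap", representation(values = "matrix"))

setValidity("EdgeMap", function(object) {
  v <- object@values
  if (any(!is.finite(v))) return("edge values must be finite")
  if (any(v < 0) || any(v > 1)) return("edge values must lie in [0, 1]")
  TRUE
})

#' Pairwise affinity field on the 4-connected pixel grid
#'
#' Stores the fuzzy affinity between each pair of 4-adjacent pixels of an
#' nr x nc image: `h[r, c]` is the affinity between (r, c) and (r, c+1),
#' `v[r, c]` between (r, c) and (r+1, c). Affinity to out-of-grid or
#' non-adjacent pixels is 0 and is not stored; self-affinity is 1 by
#' definition.
#'
#' @slot h matrix nr x (nc-1) of horizontal-pair affinities
#' @slot v matrix (nr-1) x nc of vertical-pair affinities
#' @slot dim integer(2), the underlying image dimensions
#' @export
setClass("AffinityField",
  representation(h = "matrix", v = "matrix", dim = "integer"))

setValidity("AffinityField", function(object) {
  d <- object@dim
  if (length(d) != 2L || any(d < 1L)) return("invalid image dimensions")
  if (!identical(dim(object@h), c(d[1L], d[2L] - 1L)))
    return("'h' must be nr x (nc-1)")
  if (!identical(dim(object@v), c(d[1L] - 1L, d[2L])))
    return("'v' must be (nr-1) x nc")
  if (any(object@h < 0) || any(object@h > 1) ||
      any(object@v < 0) || any(object@v > 1))
    return("affinities must lie in [0, 1]")
  TRUE
})

#' Fuzzy connectedness map
#'
#' Per-pixel strength of connectedness to a seed set: the maximum over paths
#' of the minimum affinity along the path. Seeds have connectivity 1.
#'
#' @slot values matrix in \eqn{[0, 1]}
#' @slot seeds integer matrix, one (row, col) seed per row (1-based)
#' @seealso [afcConnectivity()], [thresholdSegmentation()]
#' @export
setClass("ConnectivityMap",
  representation(values = "matrix", seeds = "matrix"))

setValidity("ConnectivityMap", function(object) {
  v <- object@values
  if (any(v < 0) || any(v > 1)) return("connectivity must lie in [0, 1]")
  s <- object@seeds
  if (ncol(s) != 2L || nrow(s) < 1L) return("seeds must be an n x 2 matrix")
  if (any(s[, 1L] < 1L) || any(s[, 1L] > nrow(v)) ||
      any(s[, 2L] < 1L) || any(s[, 2L] > ncol(v)))
    return("seeds out of bounds")
  if (any(abs(v[s] - 1) > 1e-12)) return("seed connectivity must equal 1")
  TRUE
})

#' Annotated closed boundary chain
#'
#' Ordered closed sequence of boundary points (counter-clockwise in image
#' coordinates, i.e. with row increasing downwards the traversal keeps the
#' interior on the right visually; orientation is fixed by positive shoelace
#' area in (col, -row) axes). Later stages annotate each point with its
#' c-scale chord length, inward unit normal, entry depth and object
#' thickness along the normal.
#'
#' @slot points n x 2 numeric matrix of (row, col) coordinates; implicitly
#'   closed (last point adjacent to first)
#' @slot chord numeric n, c-scale chord length per point (NA until computed)
#' @slot normals n x 2 numeric matrix of inward unit normals (NA until
#'   computed)
#' @slot entry numeric n, distance from the boundary point to the first
#'   object pixel along the inward normal
#' @slot thickness numeric n, length of the object run along the inward
#'   normal (0 where the object is absent)
#' @export
setClass("BoundaryChain",
  representation(points = "matrix", chord = "numeric", normals = "matrix",
                 entry = "numeric", thickness = "numeric"))

setValidity("BoundaryChain", function(object) {
  p <- object@points
  if (ncol(p) != 2L || nrow(p) < 3L)
    return("a closed chain needs at least 3 (row, col) points")
  if (any(duplicated(p[c(seq_len(nrow(p)), 1L), ])[
        c(FALSE, rep(TRUE, nrow(p)))] &
        rowSums(abs(p - p[c(nrow(p), seq_len(nrow(p) - 1L)), ])) == 0))
    return("repeated consecutive points")
  n <- object@normals
  if (nrow(n) > 0L) {
    len <- sqrt(rowSums(n^2))
    if (any(is.finite(len) & abs(len - 1) > 1e-6 & len > 0))
      return("normals must have unit length")
  }
  if (length(object@thickness) && any(object@thickness < 0, na.rm = TRUE))
    return("thickness must be non-negative")
  TRUE
})

setMethod("show", "BandpassSpec", function(object) {
  cat(sprintf("BandpassSpec: %s, sigma = %g (peak frequency %.4f cy/px)\n",
              object@kind, object@sigma, 1 / (object@sigma * sqrt(2))))
})

setMethod("show", "MonogenicResponse", function(object) {
  d <- dim(object@even)
  cat(sprintf("MonogenicResponse: %d x %d, sigma = %g\n",
              d[1], d[2], object@spec@sigma))
})

setMethod("show", "PhaseMaps", function(object) {
  d <- dim(object@phase)
  cat(sprintf("PhaseMaps: %d x %d (%s convention), phase range [%.3f, %.3f]\n",
              d[1], d[2], object@convention,
              min(object@phase), max(object@phase)))
})

setMethod("show", "EdgeMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("EdgeMap: %d x %d, %d non-zero pixels, max %.3f\n",
              d[1], d[2], sum(object@values > 0), max(object@values)))
})

setMethod("show", "AffinityField", function(object) {
  cat(sprintf("AffinityField on a %d x %d grid (4-connected)\n",
              object@dim[1], object@dim[2]))
})

setMethod("show", "ConnectivityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("ConnectivityMap: %d x %d, %d seed(s), mean connectivity %.3f\n",
              d[1], d[2], nrow(object@seeds), mean(object@values)))
})

setMethod("show", "BoundaryChain", function(object) {
  cat(sprintf("BoundaryChain: %d points%s%s\n", nrow(object@points),
              if (length(object@chord)) ", with c-scale chords" else "",
              if (length(object@thickness)) ", with thickness profile" else ""))
})
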