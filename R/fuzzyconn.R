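#' Affinity parameters
#'
#' Bundle of the parameters of the pairwise fuzzy affinity: the weights of
#' the homogeneity (edge) and object-feature (phase) components, and the
#' object statistics in local-phase units. Weights must sum to 1. Defaults
#' follow the fetal-arm configuration: equal weights, object phase mean
#' 2.44 rad and spread 3 x 0.086 = 0.258 rad, learned once on a small
#' training set of images.
#'
#' @param omega1 weight of the homogeneity component (1 - E)
#' @param omega2 weight of the object feature component
#' @param m_o object mean (radians of local phase, or intensity for
#'   [intensityAffinity()])
#' @param sigma_o object spread (> 0), same units as `m_o`
#' @param pairEdge how to form the pairwise edge value from the two endpoint
#'   edge values: "max" (default; an edge at either pixel cuts affinity) or
#'   "mean"
#' @return a named list of validated parameters
#' @export
affinityParams <- function(omega1 = 0.5, omega2 = 0.5, m_o = 2.44,
                           sigma_o = 3 * 0.086,
                           pairEdge = c("max", "mean")) {
  pairEdge <- match.arg(pairEdge)
  if (omega1 < 0 || omega2 < 0 || abs(omega1 + omega2 - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  if (sigma_o <= 0) stop("'sigma_o' must be positive")
  list(omega1 = omega1, omega2 = omega2, m_o = m_o, sigma_o = sigma_o,
       pairEdge = pairEdge)
}

#' Pairwise edge value between two adjacent pixels
#'
#' The thinned edge map assigns a strength per pixel; the affinity needs a
#' value per adjacent pair. The default takes the maximum of the two
#' endpoint values, so an edge at either pixel cuts the affinity between
#' them; "mean" averages instead. Symmetric in (c, d).
#'
#' @param edge an \linkS4class{EdgeMap}
#' @param c,d length-2 integer (row, col) pixel coordinates, 4-adjacent
#' @param method "max" or "mean"
#' @return scalar in \eqn{[0, 1]}
#' @export
pairEdge <- function(edge, c, d, method = c("max", "mean")) {
  method <- match.arg(method)
  stopifnot(is(edge, "EdgeMap"))
  if (sum(abs(c - d)) != 1L)
    stop("pixels must be 4-adjacent")
  v <- edge@values
  a <- v[c[1L], c[2L]]; b <- v[d[1L], d[2L]]
  if (method == "max") max(a, b) else (a + b) / 2
}

# build the pairwise object-feature component g4 for horizontal/vertical
# pairs from a per-pixel feature map
gaussObjectPair <- function(feat, m_o, sigma_o) {
  dev <- abs(feat - m_o)
  nr <- nrow(feat); nc <- ncol(feat)
  dh <- pmax(dev[, -nc, drop = FALSE], dev[, -1L, drop = FALSE])
  dv <- pmax(dev[-nr, , drop = FALSE], dev[-1L, , drop = FALSE])
  list(h = exp(-dh^2 / (2 * sigma_o^2)), v = exp(-dv^2 / (2 * sigma_o^2)))
}

pairwiseEdgeMaps <- function(E, method) {
  nr <- nrow(E); nc <- ncol(E)
  if (method == "max") {
    list(h = pmax(E[, -nc, drop = FALSE], E[, -1L, drop = FALSE]),
         v = pmax(E[-nr, , drop = FALSE], E[-1L, , drop = FALSE]))
  } else {
    list(h = (E[, -nc, drop = FALSE] + E[, -1L, drop = FALSE]) / 2,
         v = (E[-nr, , drop = FALSE] + E[-1L, , drop = FALSE]) / 2)
  }
}

#' Feature-based fuzzy affinity field
#'
#' Combines, for every 4-adjacent pixel pair (c, d), a homogeneity component
#' driven by the thinned edge map and an object-feature component driven by
#' local phase:
#' \deqn{\mu_{\kappa^*}(c,d) = \omega_1 (1 - E(c,d)) +
#'   \omega_2 \exp\!\big(-\max\{|\varphi(c)-m_o|, |\varphi(d)-m_o|\}^2 /
#'   (2\sigma_o^2)\big),}
#' with adjacency restricted to \eqn{\|c-d\| = 1} (4-connectivity), affinity
#' 1 for c = d and 0 for non-adjacent pairs. Using phase instead of
#' intensity makes the affinity contrast invariant, which is what lets one
#' parameter set serve images of very different gain.
#'
#' @param phase a \linkS4class{PhaseMaps} (folded convention expected)
#' @param edge an \linkS4class{EdgeMap} of the same shape
#' @param params from [affinityParams()]
#' @return an \linkS4class{AffinityField}
#' @seealso [afcConnectivity()], [intensityAffinity()]
#' @export
featureAffinity <- function(phase, edge, params = affinityParams()) {
  stopifnot(is(phase, "PhaseMaps"), is(edge, "EdgeMap"))
  phi <- phase@phase
  E <- edge@values
  if (!identical(dim(phi), dim(E)))
    stop("phase and edge maps must share the same shape")
  Epair <- pairwiseEdgeMaps(E, params$pairEdge)
  g4 <- gaussObjectPair(phi, params$m_o, params$sigma_o)
  new("AffinityField",
      h = params$omega1 * (1 - Epair$h) + params$omega2 * g4$h,
      v = params$omega1 * (1 - Epair$v) + params$omega2 * g4$v,
      dim = dim(phi))
}

#' Intensity-based fuzzy affinity field
#'
#' The classical affinity the feature-based one replaces, provided for
#' comparison: the homogeneity component is one minus the absolute intensity
#' difference of the pair (intensities in \eqn{[0, 1]}), and the object
#' component is the same Gaussian membership evaluated on intensities, with
#' `m_o`/`sigma_o` in intensity units. Sensitive to gain and to intensity
#' inhomogeneity, which is the failure mode that motivates the phase-based
#' affinity.
#'
#' @param image numeric matrix in \eqn{[0, 1]}
#' @param params from [affinityParams()] with intensity-unit `m_o`, `sigma_o`
#' @return an \linkS4class{AffinityField}
#' @export
intensityAffinity <- function(image, params) {
  stopifnot(is.matrix(image))
  nr <- nrow(image); nc <- ncol(image)
  dh <- abs(image[, -nc, drop = FALSE] - image[, -1L, drop = FALSE])
  dv <- abs(image[-nr, , drop = FALSE] - image[-1L, , drop = FALSE])
  g2 <- gaussObjectPair(image, params$m_o, params$sigma_o)
  new("AffinityField",
      h = params$omega1 * (1 - dh) + params$omega2 * g2$h,
      v = params$omega1 * (1 - dv) + params$omega2 * g2$v,
      dim = dim(image))
}

#' Absolute fuzzy connectedness to a seed set
#'
#' Assigns every pixel the strength of its best path to the seed set, where
#' a path's strength is the smallest pair affinity along it (weakest link)
#' and the best path is the strongest one. Seeds get connectivity 1.
#' Computed exactly by best-first label-setting propagation (the widest-path
#' variant of Dijkstra's algorithm); the result does not depend on seed
#' order or heap tie-breaking, and the connectivity of a multi-seed set is
#' the pixelwise maximum of the single-seed maps.
#'
#' @param field an \linkS4class{AffinityField}
#' @param seeds n x 2 matrix (or length-2 vector) of 1-based (row, col)
#'   seed coordinates
#' @return a \linkS4class{ConnectivityMap}
#' @examples
#' aff <- new("AffinityField", h = matrix(c(0.9, 0.4), 1), v = matrix(0, 0, 3),
#'            dim = c(1L, 3L))
#' connValues(afcConnectivity(aff, c(1, 1)))  # 1, 0.9, 0.4
#' @export
afcConnectivity <- function(field, seeds) {
  stopifnot(is(field, "AffinityField"))
  seeds <- seedMatrix(seeds)
  d <- field@dim
  if (any(seeds[, 1L] < 1L) || any(seeds[, 1L] > d[1L]) ||
      any(seeds[, 2L] < 1L) || any(seeds[, 2L] > d[2L]))
    stop("seed out of bounds")
  conn <- .afc_connectivity(field@h, field@v, seeds, d[1L], d[2L])
  new("ConnectivityMap", values = conn, seeds = seeds)
}

seedMatrix <- function(seeds) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2L, byrow = TRUE)
  seeds <- as.matrix(seeds)
  storage.mode(seeds) <- "integer"
  if (ncol(seeds) != 2L || nrow(seeds) < 1L)
    stop("'seeds' must be an n x 2 matrix of (row, col) coordinates")
  seeds
}

#' Threshold a connectivity map into a segmentation mask
#'
#' The object is the superlevel set of the connectivity map at `T_FC`
#' (default 0.85). By the max-min construction, every pixel in the mask is
#' joined to a seed by a path whose pixels all lie in the mask, so the mask
#' is a union of connected components each containing at least one seed; no
#' post-filtering is needed. Masks are nested: a higher threshold gives a
#' subset.
#'
#' @param conn a \linkS4class{ConnectivityMap}
#' @param T_FC threshold in \eqn{[0, 1]}
#' @return logical matrix
#' @export
thresholdSegmentation <- function(conn, T_FC = 0.85) {
  stopifnot(is(conn, "ConnectivityMap"), T_FC >= 0, T_FC <= 1)
  conn@values >= T_FC
}

#' Object statistics from a training region
#'
#' Mirrors the one-off training stage of the affinity: computes the mean of
#' the local phase inside a region of the object of interest and an inflated
#' spread, `sigma_o = inflate x sd`, with inflation factor 3 by default (the
#' same inflation used to turn the trained fat-phase spread 0.086 into the
#' default sigma_o = 0.258).
#'
#' @param phase a \linkS4class{PhaseMaps} or a bare feature matrix
#' @param roi logical matrix selecting the training region
#' @param inflate multiplier applied to the standard deviation
#' @return list with `m_o` and `sigma_o`
#' @export
fitObjectStats <- function(phase, roi, inflate = 3) {
  feat <- if (is(phase, "PhaseMaps")) phase@phase else phase
  stopifnot(identical(dim(feat), dim(roi)))
  vals <- feat[asBinaryMask(roi)]
  if (length(vals) < 2L) stop("training region too small")
  list(m_o = mean(vals), sigma_o = inflate * stats::sd(vals))
}
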