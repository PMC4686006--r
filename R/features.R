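#' Multi-scale feature asymmetry
#'
#' Edge measure in \eqn{[0, 1)} that is high where the odd (step-like)
#' filter response dominates the even (ridge-like) response, averaged over
#' scales:
#' \deqn{FA = \frac{1}{N}\sum_s
#'   \frac{\lfloor |odd_s| - |even_s| - T_s\rfloor}
#'        {\sqrt{even_s^2 + odd_s^2 + \epsilon}},}
#' where \eqn{|odd_s|} is the Riesz response magnitude,
#' \eqn{\lfloor\cdot\rfloor} clamps negative values to zero, \eqn{T_s}
#' suppresses spurious responses to noise and \eqn{\epsilon} avoids division
#' by zero (the square root spans the whole denominator, which guarantees
#' FA < 1). Being built from ratios of DC-free linear responses, FA is
#' contrast invariant up to the effect of the fixed threshold.
#'
#' Defaults follow the fetal-arm configuration: three scales
#' \eqn{s = 23, 25, 27} (under-30-weeks preset), \eqn{T_s = 0.155} applied
#' identically at every scale, \eqn{\epsilon = 0.01}.
#'
#' @param image numeric matrix, normalised to \eqn{[0, 1]}
#' @param scales numeric vector of bandpass sigmas (N entries)
#' @param Ts noise threshold, scalar or one value per scale
#' @param epsilon small positive stabiliser
#' @param padding boundary handling passed to [monogenicSignal()]
#' @return numeric matrix FA in \eqn{[0, 1)}
#' @seealso [modifiedNMS()] for thinning, [estimateTs()] for a data-driven
#'   threshold
#' @examples
#' img <- matrix(0.25, 64, 64); img[, 33:64] <- 0.75
#' fa <- featureAsymmetry(img)
#' @export
featureAsymmetry <- function(image, scales = c(23, 25, 27), Ts = 0.155,
                             epsilon = 0.01, padding = "mirror") {
  if (length(scales) < 1L) stop("at least one scale is required")
  if (any(Ts < 0)) stop("'Ts' must be non-negative")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  Ts <- rep_len(Ts, length(scales))
  acc <- matrix(0, nrow(image), ncol(image))
  for (i in seq_along(scales)) {
    m <- monogenicSignal(image, scales[i], padding = padding)
    oddNorm <- sqrt(m@odd1^2 + m@odd2^2)
    num <- pmax(oddNorm - abs(m@even) - Ts[i], 0)
    den <- sqrt(m@even^2 + oddNorm^2 + epsilon)
    acc <- acc + num / den
  }
  acc / length(scales)
}

#' Modified all-direction non-maximal suppression
#'
#' Classical two-neighbour non-maximal suppression evaluated in every
#' quantised direction: a pixel survives in a direction if its value is not
#' below either of the two bilinearly interpolated neighbours at unit
#' distance along that direction. Pixels surviving in at least one direction
#' keep their original value; all others are set to 0. Unlike suppression
#' restricted to the local orientation, this retains ridge crests of any
#' direction at their full FA value while thinning thick responses.
#'
#' Exact plateau ties are broken deterministically: along the negative
#' direction the comparison is strict, so a flat-topped band keeps a
#' one-pixel-wide crest (the first row/column of the plateau in scan order).
#' The operation is idempotent and never raises values.
#'
#' @param fa numeric matrix in \eqn{[0, 1]} (a feature-asymmetry map)
#' @param nDirections number of directions over \eqn{[0, \pi)}; default 8
#'   (22.5 degree steps)
#' @return an \linkS4class{EdgeMap}
#' @export
modifiedNMS <- function(fa, nDirections = 8L) {
  stopifnot(is.matrix(fa), nDirections >= 1L)
  if (any(fa < 0 | fa > 1)) stop("'fa' must lie in [0, 1]")
  nr <- nrow(fa); nc <- ncol(fa)
  idx <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  survives <- matrix(FALSE, nr, nc)
  angles <- (seq_len(nDirections) - 1L) * pi / nDirections
  for (a in angles) {
    dr <- sin(a); dc <- cos(a)
    fwd <- bilinearSample(fa, idx$r + dr, idx$c + dc)
    bwd <- bilinearSample(fa, idx$r - dr, idx$c - dc)
    ok <- as.vector(fa) > bwd & as.vector(fa) >= fwd
    survives <- survives | matrix(ok, nr, nc)
  }
  # a positive pixel with no strictly smaller back-neighbour anywhere would
  # otherwise vanish inside an exactly constant positive region; such regions
  # have no crest and are suppressed, matching the plateau rule
  out <- ifelse(survives, fa, 0)
  new("EdgeMap", values = out)
}

#' Data-driven noise threshold for feature asymmetry
#'
#' Estimates the spurious-response level of one filter scale as the mode of
#' the local-energy distribution \eqn{\sqrt{even^2 + odd^2}}, approximated
#' by the midpoint of the fullest Freedman--Diaconis histogram bin. Offered
#' as an alternative to the fixed default threshold (0.155); the default
#' analysis pathway does not call this.
#'
#' @param even,oddNorm matrices from one scale of one image
#' @return scalar threshold estimate (0 for degenerate constant maps)
#' @export
estimateTs <- function(even, oddNorm) {
  stopifnot(identical(dim(even), dim(oddNorm)))
  energy <- as.vector(sqrt(even^2 + oddNorm^2))
  if (max(energy) - min(energy) < 1e-15) return(0)
  iqr <- stats::IQR(energy)
  if (iqr <= 0) return(0)
  bw <- 2 * iqr / length(energy)^(1 / 3)
  breaks <- seq(min(energy), max(energy) + bw, by = bw)
  h <- graphics::hist(energy, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}
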