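# Deterministic synthetic phantom of a fetal-arm cross-section: a bright
# echodense fat ring around hypoechoic muscle, a small bright bone at the
# centre casting a dark wedge shadow that interrupts the ring, multiplicative
# speckle, and a smooth intensity inhomogeneity field.  Region labels:
# 1 background, 2 adipose (fat ring), 3 muscle, 4 bone, 5 shadow.

#' Phantom specification
#'
#' Geometry and appearance of the synthetic fetal-arm phantom. Defaults
#' describe a 256 x 256 image with a fat annulus of outer radius 100 and
#' thickness 26, a bone of radius 12 at the arm centre, a 40 degree shadow
#' wedge cast downwards (away from the probe), mean intensities
#' (background 0.10, fat 0.75, muscle 0.18, bone 0.95, shadow 0.04),
#' multiplicative speckle of scale 0.10 and a smooth multiplicative
#' inhomogeneity of amplitude 0.08. The fat-ring thickness is commensurate
#' with the structures the default filter scales (sigma 23--27) respond to.
#'
#' @param size image side length in pixels
#' @param centre arm centre (row, col); default image centre
#' @param rOuter outer radius of the fat ring
#' @param fatThickness thickness of the fat ring in pixels
#' @param rBone bone radius
#' @param shadowDeg full opening angle of the shadow wedge in degrees
#' @param means named intensities in \eqn{[0,1]} for background, fat,
#'   muscle, bone, shadow
#' @param speckle multiplicative speckle scale (0 disables)
#' @param inhomogeneity amplitude of the smooth multiplicative field
#'   (0 disables)
#' @param seed integer random seed; the same spec and seed always produce a
#'   bit-identical image
#' @return a validated list of phantom parameters
#' @export
phantomSpec <- function(size = 256L, centre = NULL, rOuter = 100,
                        fatThickness = 26, rBone = 12, shadowDeg = 40,
                        means = c(background = 0.10, fat = 0.75,
                                  muscle = 0.18, bone = 0.95, shadow = 0.04),
                        speckle = 0.10, inhomogeneity = 0.08, seed = 7L) {
  if (is.null(centre)) centre <- c((size + 1) / 2, (size + 1) / 2)
  rInner <- rOuter - fatThickness
  if (!(rBone > 0 && rBone < rInner && rInner < rOuter && rOuter < size / 2))
    stop("invalid geometry: need 0 < rBone < rInner < rOuter < size/2")
  needed <- c("background", "fat", "muscle", "bone", "shadow")
  if (!all(needed %in% names(means)))
    stop("'means' must name: ", paste(needed, collapse = ", "))
  if (any(means < 0 | means > 1)) stop("intensities must lie in [0, 1]")
  if (speckle < 0 || inhomogeneity < 0)
    stop("noise amplitudes must be non-negative")
  list(size = as.integer(size), centre = centre, rOuter = rOuter,
       rInner = rInner, rBone = rBone, shadowDeg = shadowDeg,
       means = means, speckle = speckle, inhomogeneity = inhomogeneity,
       seed = as.integer(seed))
}

#' Generate the synthetic fetal-arm phantom
#'
#' Composes the region template (annular fat ring, muscle core, central
#' bone, downward shadow wedge), multiplies in a smooth low-frequency
#' inhomogeneity field and seeded multiplicative speckle (a Rayleigh
#' variate passed through a square-root compression, standardised and
#' scaled), and clips to \eqn{[0, 1]}. The shadow wedge replaces fat and
#' muscle beneath the bone with near-zero signal, interrupting the ring the
#' way an acoustic shadow does. All randomness derives from `spec$seed`.
#'
#' @param spec from [phantomSpec()]
#' @return list with `image` (matrix in \eqn{[0,1]}), `labels` (integer
#'   matrix), `legend` (named labels including the four quality-assessment
#'   regions), and `truth` (logical matrix: the gap-free fat annulus)
#' @examples
#' ph <- makePhantom(phantomSpec(seed = 7))
#' table(ph$labels)
#' @export
makePhantom <- function(spec = phantomSpec()) {
  n <- spec$size
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dr <- rows - spec$centre[1L]
  dc <- cols - spec$centre[2L]
  rad <- sqrt(dr^2 + dc^2)
  # angle from straight down (probe above, shadow cast downwards)
  ang <- abs(atan2(dc, dr))  # 0 = straight down, pi = straight up
  halfWedge <- spec$shadowDeg / 2 * pi / 180

  labels <- matrix(1L, n, n)                        # background
  labels[rad <= spec$rOuter] <- 2L                  # fat ring
  labels[rad <= spec$rInner] <- 3L                  # muscle
  labels[rad <= spec$rBone] <- 4L                   # bone
  shadow <- rad > spec$rBone & rad <= spec$rOuter & ang <= halfWedge
  labels[shadow] <- 5L

  lut <- c(spec$means[["background"]], spec$means[["fat"]],
           spec$means[["muscle"]], spec$means[["bone"]],
           spec$means[["shadow"]])
  template <- matrix(lut[labels], n, n)

  img <- template
  set.seed(spec$seed)
  if (spec$inhomogeneity > 0) {
    # smooth low-frequency field: a seeded mixture of plane-wave cosines
    # (about one cycle per image), normalised to unit peak
    field <- matrix(0, n, n)
    for (j in 1:3) {
      f <- stats::runif(2, -1.5, 1.5) / n
      phs <- stats::runif(1, 0, 2 * pi)
      field <- field + stats::runif(1, 0.5, 1) *
        cos(2 * pi * (f[1L] * rows + f[2L] * cols) + phs)
    }
    field <- field / max(abs(field))
    img <- img * (1 + spec$inhomogeneity * field)
  }
  if (spec$speckle > 0) {
    ray <- sqrt(-2 * log(stats::runif(n * n)))     # Rayleigh(1)
    sqz <- sqrt(ray)                               # compression-like mapping
    sqz <- (sqz - mean(sqz)) / stats::sd(sqz)
    img <- img * (1 + spec$speckle * matrix(sqz, n, n))
  }
  img <- pmin(pmax(img, 0), 1)

  truth <- rad <= spec$rOuter & rad > spec$rInner   # gap-free annulus
  list(image = img, labels = labels,
       legend = c(background = 1L, adipose = 2L, muscle = 3L, bone = 4L,
                  shadow = 5L),
       truth = truth)
}

#' Binary annulus fixture with wedge gaps
#'
#' Deterministic rasterised annulus with `k` equally spaced angular wedges
#' removed; the standard test bed for the gap detection and completion
#' machinery.
#'
#' @param k number of wedges (0 for a full annulus)
#' @param wedgeDeg full opening angle of each wedge in degrees
#' @param rOuter,rInner annulus radii (rInner 0 gives a disk)
#' @param size image side length
#' @param rotateDeg rotate the wedge pattern (degrees)
#' @return logical matrix
#' @export
makeGapFixture <- function(k = 1L, wedgeDeg = 60, rOuter = 80, rInner = 55,
                           size = 200L, rotateDeg = 0) {
  if (k < 0) stop("'k' must be non-negative")
  if (k > 0 && k * wedgeDeg >= 360)
    stop("overlapping wedges: k * wedgeDeg must be < 360")
  n <- as.integer(size)
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  rad <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  mask <- rad <= rOuter & rad > rInner
  if (k > 0) {
    theta <- (atan2(cols - ctr, -(rows - ctr)) * 180 / pi) %% 360
    centres <- (seq_len(k) - 1L) * 360 / k + rotateDeg
    for (a in centres) {
      d <- abs(((theta - a + 180) %% 360) - 180)
      mask[mask & d <= wedgeDeg / 2] <- FALSE
    }
  }
  mask
}

#' Gain/offset/gamma contrast transform
#'
#' \eqn{clip(a \cdot image^\gamma + c,\ 0,\ 1)}. With gamma = 1 and values
#' kept inside \eqn{[0, 1]} this is exactly the transformation local phase
#' and feature asymmetry are invariant to.
#'
#' @param image numeric matrix
#' @param a gain (> 0)
#' @param c offset
#' @param gamma exponent (> 0)
#' @param clip clip the result to \eqn{[0, 1]} (default TRUE); set FALSE to
#'   preserve exact linearity for invariance checks
#' @return numeric matrix
#' @export
contrastTransform <- function(image, a = 1, c = 0, gamma = 1, clip = TRUE) {
  if (a <= 0 || gamma <= 0) stop("'a' and 'gamma' must be positive")
  out <- a * image^gamma + c
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}
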