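#' Regional gray-level entropy
#'
#' Shannon entropy in bits of the gray-level distribution inside a region:
#' the normalised histogram over `M` levels gives
#' \eqn{H = -\sum_k p_k \log_2 p_k} (with \eqn{0\log 0 := 0}). Entropies are
#' computed on quantised 8-bit levels (M = 256 by default), not on
#' normalised floats, so \eqn{0 \le H \le \log_2 M = 8} bits. Entropy
#' quantifies the information content (texture complexity) of a region
#' independently of contrast or absolute intensity.
#'
#' @param image numeric matrix in \eqn{[0, 1]} or an integer-level matrix
#' @param region logical matrix selecting the region (non-empty)
#' @param M number of gray levels (default 256)
#' @return entropy in bits
#' @examples
#' img <- matrix(runif(64 * 64), 64)
#' regionEntropy(img, matrix(TRUE, 64, 64))
#' @export
regionEntropy <- function(image, region, M = 256L) {
  region <- asBinaryMask(region)
  if (!any(region)) stop("empty region")
  stopifnot(identical(dim(image), dim(region)))
  vals <- image[region]
  levels <- quantiseLevels(vals, M)
  p <- tabulate(levels + 1L, nbins = M) / length(levels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# map intensities to integer levels 0..M-1; float images in [0,1] are
# quantised, integer-valued images are used as-is (clipped)
quantiseLevels <- function(vals, M) {
  if (all(vals == round(vals)) && max(vals) > 1) {
    lev <- pmin(pmax(round(vals), 0), M - 1L)
  } else {
    lev <- pmin(pmax(round(vals * (M - 1L)), 0), M - 1L)
  }
  as.integer(lev)
}

#' Entropy-based image quality scores
#'
#' Computes the per-region entropies of an image partitioned into the four
#' anatomical regions (background, adipose, muscle, bone) and the two
#' interface scores
#' \deqn{S_{ab} = H(A_{adipose}) - H(A_{background}), \qquad
#'       S_{am} = H(A_{adipose}) - H(A_{muscle}).}
#' Low scores mean the adjacent regions carry similar information content,
#' i.e. the interface the segmentation must find is weak and overall image
#' quality is lower; high scores mean distinct regions and higher quality.
#'
#' @param image numeric matrix
#' @param labels integer matrix of region labels aligned with `image`
#' @param legend named integer vector mapping region names to labels; must
#'   name at least `background`, `adipose`, `muscle` and `bone`
#' @param M number of gray levels (default 256)
#' @return list with `entropy` (named vector, bits), `S_ab` and `S_am`
#' @export
qualityScores <- function(image, labels,
                          legend = c(background = 1L, adipose = 2L,
                                     muscle = 3L, bone = 4L),
                          M = 256L) {
  stopifnot(identical(dim(image), dim(labels)))
  required <- c("background", "adipose", "muscle", "bone")
  missingNames <- setdiff(required, names(legend))
  if (length(missingNames))
    stop("legend missing region(s): ", paste(missingNames, collapse = ", "))
  H <- vapply(required, function(nm) {
    reg <- labels == legend[[nm]]
    if (!any(reg))
      stop(sprintf("region '%s' (label %d) absent from the label map",
                   nm, legend[[nm]]))
    regionEntropy(image, reg, M = M)
  }, numeric(1))
  list(entropy = H,
       S_ab = unname(H["adipose"] - H["background"]),
       S_am = unname(H["adipose"] - H["muscle"]))
}
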