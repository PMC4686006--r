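#' Region-based segmentation agreement
#'
#' Area-overlap measures of a test mask against a reference delineation:
#' sensitivity is the true positive area fraction
#' \eqn{TPAF = |T \cap R| / |R|}, specificity is \eqn{1 - FPAF} with the
#' false positive area fraction \eqn{FPAF = |T \setminus R| / |R|}
#' (reference-area denominator), and Dice is
#' \eqn{2|T \cap R| / (|T| + |R|)}.
#'
#' @param test,ref binary matrices of the same shape; `ref` non-empty
#' @return list with `tpaf` (sensitivity), `fpaf`, `specificity` and `dice`
#' @examples
#' R <- matrix(FALSE, 3, 3); R[1:2, ] <- TRUE   # 6 px
#' T <- matrix(FALSE, 3, 3); T[2:3, ] <- TRUE; T[3, 3] <- FALSE  # 5 px
#' areaOverlap(T, R)  # tpaf 4/6, dice 8/11
#' @export
areaOverlap <- function(test, ref) {
  test <- asBinaryMask(test); ref <- asBinaryMask(ref)
  stopifnot(identical(dim(test), dim(ref)))
  stopIfEmptyMask(ref, "reference mask")
  inter <- sum(test & ref)
  tpaf <- inter / sum(ref)
  fpaf <- sum(test & !ref) / sum(ref)
  list(tpaf = tpaf, fpaf = fpaf, specificity = 1 - fpaf,
       dice = 2 * inter / (sum(test) + sum(ref)))
}

#' Repeatability precision of two segmentation runs
#'
#' Overlap of two runs of the same method (e.g. with different seed
#' placements): \eqn{|T_1 \cap T_2| / |T_1 \cup T_2|}. 1 means the runs
#' are identical.
#'
#' @param t1,t2 binary matrices of the same shape
#' @return scalar in \eqn{[0, 1]}
#' @export
maskPrecision <- function(t1, t2) {
  t1 <- asBinaryMask(t1); t2 <- asBinaryMask(t2)
  stopifnot(identical(dim(t1), dim(t2)))
  u <- sum(t1 | t2)
  if (u == 0) stop("both masks are empty")
  sum(t1 & t2) / u
}

# 4-connected inner boundary pixels of a mask, as an n x 2 (row, col) matrix
innerBoundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(mask & !core, arr.ind = TRUE)
}

#' Symmetric contour distances between two masks
#'
#' Extracts the 4-connected inner boundary pixels of both masks, pools the
#' nearest-neighbour distances from each boundary to the other (symmetric
#' pooling, so the metrics do not depend on argument order), scales by the
#' pixel spacing, and reports the maximum (MSD), mean (ASD) and
#' root-mean-square (RMSD) symmetric contour distances. By the power-mean
#' inequality ASD <= RMSD <= MSD.
#'
#' Nearest-neighbour distances are computed exactly via the Euclidean
#' distance transform of each boundary set.
#'
#' @param test,ref binary matrices of the same shape, both non-empty
#' @param spacing pixel spacing in mm (default 1)
#' @return list with `msd`, `asd`, `rmsd` in mm
#' @export
contourDistances <- function(test, ref, spacing = 1) {
  test <- asBinaryMask(test); ref <- asBinaryMask(ref)
  stopifnot(identical(dim(test), dim(ref)), spacing > 0)
  stopIfEmptyMask(test, "test mask"); stopIfEmptyMask(ref, "reference mask")
  bt <- innerBoundary(test); br <- innerBoundary(ref)
  dTtoR <- distToSet(bt, br, dim(test))
  dRtoT <- distToSet(br, bt, dim(test))
  d <- c(dTtoR, dRtoT) * spacing
  list(msd = max(d), asd = mean(d), rmsd = sqrt(mean(d^2)))
}

# exact Euclidean distance from each point in `from` to the set `to`,
# via the distance transform of the complement of `to`
distToSet <- function(from, to, dims) {
  img <- matrix(1, dims[1L], dims[2L])
  img[to] <- 0
  dt <- as.matrix(EBImage::distmap(img, metric = "euclidean"))
  dt[from]
}
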