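#' Run the full feature-based segmentation pipeline
#'
#' Executes the stages in order: monogenic signal and local phase at the
#' configured scale; multi-scale feature asymmetry and modified non-maximal
#' suppression giving the thinned edge map; feature-based affinity and
#' absolute fuzzy connectedness from the seed set; thresholding at `T_FC`;
#' shadow-gap completion; mean curvature flow regularisation.
#'
#' If `fitRoi` is given (a logical matrix, or a seed-centred disc radius),
#' the object phase statistics `m_o`/`sigma_o` are re-estimated from that
#' region with [fitObjectStats()] before building the affinity, mirroring
#' the one-off training stage; otherwise the configured defaults are used.
#'
#' The pipeline is fully deterministic: identical inputs give identical
#' outputs.
#'
#' @param image numeric matrix in \eqn{[0, 1]}
#' @param seeds n x 2 matrix (or length-2 vector) of 1-based (row, col)
#'   seeds inside the object of interest (1--5 seeds expected; more are
#'   accepted with a warning)
#' @param config from [defaultConfig()] or [loadConfig()]
#' @param fitRoi optional training region: a logical matrix, or a numeric
#'   radius for a disc centred on the first seed
#' @param truth optional reference mask; if supplied, evaluation metrics
#'   are included in the result
#' @param spacing pixel spacing in mm for distance metrics
#' @return list with `mask` (final), `premask` (before completion),
#'   `completed` (before smoothing), `connectivity`
#'   (\linkS4class{ConnectivityMap}), `edge` (\linkS4class{EdgeMap}), `fa`,
#'   `phase` (\linkS4class{PhaseMaps}), `params` (affinity parameters
#'   actually used), and `metrics` (if `truth` given)
#' @examples
#' \donttest{
#' ph <- makePhantom()
#' res <- runPipeline(ph$image, seeds = c(42, 128), fitRoi = 6,
#'                    truth = ph$truth)
#' res$metrics$dice
#' }
#' @export
runPipeline <- function(image, seeds, config = defaultConfig(),
                        fitRoi = NULL, truth = NULL, spacing = 1) {
  stopifnot(is.matrix(image))
  seeds <- seedMatrix(seeds)
  if (any(seeds[, 1L] < 1L) || any(seeds[, 1L] > nrow(image)) ||
      any(seeds[, 2L] < 1L) || any(seeds[, 2L] > ncol(image)))
    stop("stage fuzzyconn: seed outside the image")
  if (nrow(seeds) > 5L)
    warning("more than 5 seeds supplied; the method is designed for 1-5")

  # local phase at the single configured scale
  mono <- monogenicSignal(image, config$phase$sigma,
                          padding = config$phase$padding)
  ph <- phaseMaps(mono, convention = config$phase$convention)

  # multi-scale feature asymmetry, thinned
  fa <- featureAsymmetry(image, scales = config$fa$scales,
                         Ts = config$fa$Ts, epsilon = config$fa$epsilon,
                         padding = config$phase$padding)
  edge <- modifiedNMS(fa, nDirections = config$fa$nms_directions)

  # affinity + connectivity
  params <- affinityParams(omega1 = config$fc$omega1,
                           omega2 = config$fc$omega2,
                           m_o = config$fc$m_o, sigma_o = config$fc$sigma_o,
                           pairEdge = config$fc$pair_edge)
  if (!is.null(fitRoi)) {
    roi <- if (is.matrix(fitRoi)) fitRoi else
      discMask(dim(image), seeds[1L, ], fitRoi)
    st <- fitObjectStats(ph, roi)
    params$m_o <- st$m_o
    params$sigma_o <- st$sigma_o
  }
  field <- featureAffinity(ph, edge, params)
  conn <- afcConnectivity(field, seeds)
  premask <- thresholdSegmentation(conn, config$fc$T_FC)
  if (!any(premask))
    stop("stage fuzzyconn: empty segmentation at T_FC = ", config$fc$T_FC)

  completed <- completeObject(premask, t = config$completion$t,
                              D = config$completion$D,
                              minGapLen = config$completion$min_gap_len)
  mask <- mcfSmooth(completed, nIter = config$mcf$n_iter,
                    dt = config$mcf$dt)

  out <- list(mask = mask, premask = premask, completed = completed,
              connectivity = conn, edge = edge, fa = fa, phase = ph,
              params = params)
  if (!is.null(truth)) {
    out$metrics <- c(areaOverlap(mask, truth),
                     contourDistances(mask, truth, spacing = spacing))
  }
  out
}

# disc-shaped logical mask of given radius around a (row, col) centre
discMask <- function(dims, centre, radius) {
  rows <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  cols <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  (rows - centre[1L])^2 + (cols - centre[2L])^2 <= radius^2
}

#' Save pipeline intermediates to disk
#'
#' Writes the final and intermediate maps of a [runPipeline()] result:
#' masks as 8-bit PNG, continuous maps (FA, phase, connectivity) as 32-bit
#' float TIFF.
#'
#' @param res a [runPipeline()] result
#' @param dir output directory (created if needed)
#' @param prefix filename prefix
#' @return invisibly, the vector of files written
#' @export
saveIntermediates <- function(res, dir, prefix = "fcseg") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name, ext) file.path(dir, sprintf("%s_%s.%s", prefix, name, ext))
  files <- c(
    writeMask(res$mask, p("mask", "png")),
    writeMask(res$premask, p("premask", "png")),
    writeMask(res$completed, p("completed", "png")),
    writeFloatMap(connValues(res$connectivity), p("connectivity", "tif")),
    writeFloatMap(edgeValues(res$edge), p("edge", "tif")),
    writeFloatMap(res$fa, p("fa", "tif")),
    writeFloatMap(phaseMap(res$phase) / pi, p("phase", "tif")))
  invisible(files)
}
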