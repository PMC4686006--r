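# Pipeline configuration: every stage parameter with its default, the two
# gestational-age presets, and YAML round-trip with validation.

configDefaults <- function() {
  list(
    phase = list(sigma = 27, convention = "folded", padding = "mirror"),
    fa = list(scales = c(23, 25, 27), Ts = 0.155, epsilon = 0.01,
              nms_directions = 8L),
    fc = list(omega1 = 0.5, omega2 = 0.5, m_o = 2.44, sigma_o = 0.258,
              T_FC = 0.85, pair_edge = "max"),
    completion = list(t = 5, D = 5L, min_gap_len = 3L),
    mcf = list(n_iter = 25L, dt = 0.2),
    quality = list(M = 256L)
  )
}

#' Default pipeline configuration
#'
#' Returns the full parameter set of the segmentation pipeline with the
#' fetal-arm defaults: local-phase scale sigma = 27, feature-asymmetry
#' scales (23, 25, 27) with Ts = 0.155 and epsilon = 0.01, affinity weights
#' 0.5/0.5 with object phase statistics m_o = 2.44 and sigma_o = 0.258,
#' connectivity threshold T_FC = 0.85, c-scale threshold t = 5, anchor
#' distance D = 5, and 25 curvature-flow iterations at dt = 0.2.
#'
#' Two presets adapt the filter scales to the size of the structures:
#' `"under30"` (the default scales above, gestational age below 30 weeks)
#' and `"over30"` (phase sigma 35, FA scales 27, 30, 35).
#'
#' @param preset `"under30"` (default) or `"over30"`
#' @return nested named list of parameters
#' @examples
#' cfg <- defaultConfig("over30")
#' cfg$fa$scales
#' @export
defaultConfig <- function(preset = c("under30", "over30")) {
  preset <- match.arg(preset)
  cfg <- configDefaults()
  if (preset == "over30") {
    cfg$phase$sigma <- 35
    cfg$fa$scales <- c(27, 30, 35)
  }
  cfg
}

validateConfig <- function(cfg) {
  ref <- configDefaults()
  extraTop <- setdiff(names(cfg), names(ref))
  if (length(extraTop))
    stop("unknown config section(s): ", paste(extraTop, collapse = ", "))
  for (sec in names(cfg)) {
    extra <- setdiff(names(cfg[[sec]]), names(ref[[sec]]))
    if (length(extra))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(extra, collapse = ", ")))
  }
  merged <- ref
  for (sec in names(cfg))
    merged[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  # normalise storage types so that save/load round-trips compare equal
  for (key in c("sigma")) merged$phase[[key]] <- as.numeric(merged$phase[[key]])
  merged$fa$scales <- as.numeric(merged$fa$scales)
  merged$fa$Ts <- as.numeric(merged$fa$Ts)
  merged$fa$epsilon <- as.numeric(merged$fa$epsilon)
  merged$fa$nms_directions <- as.integer(merged$fa$nms_directions)
  for (key in c("omega1", "omega2", "m_o", "sigma_o", "T_FC"))
    merged$fc[[key]] <- as.numeric(merged$fc[[key]])
  merged$completion$t <- as.numeric(merged$completion$t)
  merged$completion$D <- as.integer(merged$completion$D)
  merged$completion$min_gap_len <- as.integer(merged$completion$min_gap_len)
  merged$mcf$n_iter <- as.integer(merged$mcf$n_iter)
  merged$mcf$dt <- as.numeric(merged$mcf$dt)
  merged$quality$M <- as.integer(merged$quality$M)
  with(merged, {
    stopifnot(phase$sigma > 0, length(fa$scales) >= 1, fa$Ts >= 0,
              fa$epsilon > 0, fc$sigma_o > 0,
              abs(fc$omega1 + fc$omega2 - 1) < 1e-9,
              fc$T_FC >= 0, fc$T_FC <= 1,
              completion$t > 0, completion$D >= 1,
              mcf$dt > 0, mcf$dt <= 0.25, mcf$n_iter >= 0)
  })
  merged
}

#' Load / save a pipeline configuration
#'
#' YAML serialisation of the configuration. Loading merges the file over
#' the defaults, validates ranges and rejects unknown keys;
#' `loadConfig(saveConfig(cfg))` round-trips.
#'
#' @param path YAML file path
#' @return `loadConfig`: the validated nested list; `saveConfig`:
#'   invisibly, `path`
#' @export
loadConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateConfig(cfg)
}

#' @param cfg a configuration list
#' @rdname loadConfig
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
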