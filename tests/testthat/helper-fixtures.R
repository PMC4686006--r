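# Shared fixtures and independent oracles for the test suite.

# step image: left value lo, right value hi, step after column `at`
stepImage <- function(n = 128, at = n / 2, lo = 0.25, hi = 0.75) {
  img <- matrix(lo, n, n)
  img[, (at + 1):n] <- hi
  img
}

# random 4-connected affinity field on an nr x nc grid
randomField <- function(nr, nc) {
  new("AffinityField",
      h = matrix(stats::runif(nr * (nc - 1)), nr, nc - 1),
      v = matrix(stats::runif((nr - 1) * nc), nr - 1, nc),
      dim = c(as.integer(nr), as.integer(nc)))
}

# independent max-min connectivity oracle: exhaustive DFS over all simple
# paths from the seed set, tracking the minimum affinity along each path
bruteForceConnectivity <- function(field, seeds) {
  nr <- field@dim[1]; nc <- field@dim[2]
  best <- matrix(0, nr, nc)
  visited <- matrix(FALSE, nr, nc)
  aff <- function(r1, c1, r2, c2) {
    if (r1 == r2) field@h[r1, min(c1, c2)] else field@v[min(r1, r2), c1]
  }
  dfs <- function(r, c, strength) {
    if (strength > best[r, c]) best[r, c] <<- strength
    visited[r, c] <<- TRUE
    for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || visited[r2, c2]) next
      dfs(r2, c2, min(strength, aff(r, c, r2, c2)))
    }
    visited[r, c] <<- FALSE
  }
  for (i in seq_len(nrow(seeds))) {
    best[seeds[i, 1], seeds[i, 2]] <- 1
    dfs(seeds[i, 1], seeds[i, 2], 1)
  }
  best
}

# 90-degree counter-clockwise rotation of a matrix
rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# phantom shared across tests (generation is cheap but not free)
defaultPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makePhantom(phantomSpec(seed = 7))
    cache
  }
})

# train-once object statistics on the phantom fat layer: a disc spanning
# the layer cross-section centred on a seed inside the ring
trainedConfig <- function(ph, seed = c(42, 128), radius = 13) {
  cfg <- defaultConfig()
  pm <- phaseMaps(monogenicSignal(ph$image, cfg$phase$sigma))
  roi <- fcseg:::discMask(dim(ph$image), seed, radius)
  st <- fitObjectStats(pm, roi)
  cfg$fc$m_o <- st$m_o
  cfg$fc$sigma_o <- st$sigma_o
  cfg
}
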