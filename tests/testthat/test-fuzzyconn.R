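makePhase <- function(values) {
  m <- matrix(values, nrow = 1)
  new("PhaseMaps", amplitude = m * 0 + 1, phase = m,
      orientation = m * 0, convention = "folded")
}

makeEdge <- function(values) new("EdgeMap", values = matrix(values, nrow = 1))

test_that("pairwise edge value is the endpoint maximum and symmetric", {
  e <- makeEdge(c(0.2, 0.9, 0))
  expect_identical(pairEdge(e, c(1, 1), c(1, 2)), 0.9)
  expect_identical(pairEdge(e, c(1, 2), c(1, 1)), 0.9)
  expect_identical(pairEdge(e, c(1, 2), c(1, 3)), 0.9)
  expect_identical(pairEdge(e, c(1, 2), c(1, 3), method = "mean"), 0.45)
  expect_error(pairEdge(e, c(1, 1), c(1, 3)), "adjacent")
})

test_that("affinity arithmetic matches hand calculations exactly", {
  p <- affinityParams(m_o = 2.44, sigma_o = 0.258)

  # both components maximal: affinity 1
  f <- featureAffinity(makePhase(c(2.44, 2.44)), makeEdge(c(0, 0)), p)
  expect_equal(f@h[1, 1], 1, tolerance = 1e-15)

  # omega 0.5/0.5, E = 0.5, one phase at m_o + sigma_o:
  # 0.5*0.5 + 0.5*exp(-1/2)
  f <- featureAffinity(makePhase(c(2.44, 2.44 + 0.258)),
                       makeEdge(c(0.5, 0.5)), p)
  expect_equal(f@h[1, 1], 0.25 + 0.5 * exp(-0.5), tolerance = 1e-12)

  # E = 1 kills the homogeneity term entirely
  f <- featureAffinity(makePhase(c(2.44, 3.0)), makeEdge(c(1, 1)), p)
  expect_equal(f@h[1, 1], 0.5 * exp(-(3.0 - 2.44)^2 / (2 * 0.258^2)),
               tolerance = 1e-12)
  expect_lte(f@h[1, 1], 0.5)

  expect_error(affinityParams(omega1 = 0.7, omega2 = 0.5), "sum to 1")
})

test_that("affinity fields are symmetric by construction and in [0, 1]", {
  set.seed(5)
  phi <- matrix(runif(30, 0, pi), 5, 6)
  E <- matrix(runif(30), 5, 6)
  pm <- new("PhaseMaps", amplitude = phi * 0 + 1, phase = phi,
            orientation = phi * 0, convention = "folded")
  f <- featureAffinity(pm, new("EdgeMap", values = E),
                       affinityParams(m_o = 1, sigma_o = 0.5))
  expect_true(validObject(f))
  # symmetry is structural: h[r, c] serves both (r,c)->(r,c+1) and back;
  # check the max-rule agrees when evaluated from either endpoint
  expect_equal(f@h[2, 3],
               0.5 * (1 - max(E[2, 3], E[2, 4])) +
               0.5 * exp(-max(abs(phi[2, 3] - 1), abs(phi[2, 4] - 1))^2 /
                         (2 * 0.25)))
})

test_that("connectivity follows the weakest link on a 1 x 3 grid", {
  f <- new("AffinityField", h = matrix(c(0.9, 0.4), 1),
           v = matrix(numeric(0), 0, 3), dim = c(1L, 3L))
  cm <- afcConnectivity(f, c(1, 1))
  expect_equal(as.vector(connValues(cm)), c(1, 0.9, 0.4))
  expect_error(afcConnectivity(f, c(1, 7)), "bounds")
})

test_that("connectivity matches exhaustive path enumeration on random grids", {
  set.seed(123)
  for (i in 1:30) {
    f <- randomField(4, 4)
    seeds <- matrix(c(sample(4, 1), sample(4, 1)), ncol = 2)
    fast <- connValues(afcConnectivity(f, seeds))
    slow <- bruteForceConnectivity(f, seeds)
    expect_equal(fast, slow, tolerance = 1e-15)
  }
})

test_that("connectivity is monotone, seed-order invariant, and max-composable", {
  set.seed(77)
  f <- randomField(5, 5)
  s1 <- matrix(c(1, 1), ncol = 2)
  s2 <- matrix(c(4, 5), ncol = 2)
  both <- rbind(s1, s2)
  c1 <- connValues(afcConnectivity(f, s1))
  c2 <- connValues(afcConnectivity(f, s2))
  cb <- connValues(afcConnectivity(f, both))
  expect_equal(cb, pmax(c1, c2), tolerance = 1e-15)
  expect_equal(cb, connValues(afcConnectivity(f, both[2:1, ])),
               tolerance = 1e-15)

  # raising one pair affinity never decreases any connectivity value
  f2 <- f
  f2@h[3, 2] <- min(1, f2@h[3, 2] + 0.3)
  expect_true(all(connValues(afcConnectivity(f2, s1)) >= c1 - 1e-15))
})

test_that("thresholded masks are nested and their components contain seeds", {
  set.seed(9)
  f <- randomField(8, 8)
  seeds <- matrix(c(2, 2, 7, 6), ncol = 2, byrow = TRUE)
  cm <- afcConnectivity(f, seeds)
  expect_true(all(thresholdSegmentation(cm, 0) == TRUE))
  m1 <- thresholdSegmentation(cm, 0.3)
  m2 <- thresholdSegmentation(cm, 0.6)
  expect_true(all(m1[m2]))                 # nestedness
  expect_true(all(m2[seeds]))              # seeds always included
  lab <- EBImage::bwlabel(m2 * 1)
  seedLabs <- lab[seeds]
  expect_true(all(sort(unique(lab[lab > 0])) %in% seedLabs))
})

test_that("intensity affinity reproduces the classical baseline behaviour", {
  p <- affinityParams(m_o = 0.5, sigma_o = 0.2)
  const <- matrix(0.5, 4, 4)
  f <- intensityAffinity(const, p)
  expect_true(all(abs(f@h - 1) < 1e-12) && all(abs(f@v - 1) < 1e-12))

  chk <- outer(1:6, 1:6, function(r, c) (r + c) %% 2) * 0.8 + 0.1
  fc <- intensityAffinity(chk, affinityParams(m_o = 0.5, sigma_o = 0.5))
  expect_true(all(fc@h < 1 - 1e-6))
})

test_that("object statistics fit mirrors the training-stage inflation", {
  set.seed(2)
  phi <- matrix(rnorm(400, mean = 2.4, sd = 0.08), 20, 20)
  roi <- matrix(TRUE, 20, 20)
  st <- fitObjectStats(phi, roi)
  expect_equal(st$m_o, mean(phi), tolerance = 1e-12)
  expect_equal(st$sigma_o, 3 * sd(phi), tolerance = 1e-12)
})
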