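test_that("area overlap matches counting oracles", {
  R <- matrix(FALSE, 3, 3); R[1:2, ] <- TRUE                 # 6 px
  T1 <- matrix(FALSE, 3, 3); T1[2:3, ] <- TRUE; T1[3, 3] <- FALSE  # 5 px, 3 overlap
  # overlap: row 2 entirely (3 px) + row 3 none of R -> |T inter R| = 3
  ov <- areaOverlap(T1, R)
  expect_equal(ov$tpaf, 3 / 6, tolerance = 1e-15)
  expect_equal(ov$dice, 2 * 3 / (5 + 6), tolerance = 1e-15)

  # the 4-overlap toy case
  R2 <- matrix(FALSE, 3, 3); R2[, 1:2] <- TRUE               # 6 px
  T2 <- matrix(FALSE, 3, 3); T2[1:2, 1:2] <- TRUE; T2[3, 3] <- TRUE  # 5 px
  ov2 <- areaOverlap(T2, R2)
  expect_equal(ov2$tpaf, 4 / 6, tolerance = 1e-15)
  expect_equal(ov2$dice, 8 / 11, tolerance = 1e-15)
  expect_equal(ov2$specificity, 1 - 1 / 6, tolerance = 1e-15)

  same <- areaOverlap(R, R)
  expect_identical(c(same$tpaf, same$specificity, same$dice), c(1, 1, 1))
  disjoint <- matrix(FALSE, 3, 3); disjoint[3, ] <- TRUE
  expect_identical(areaOverlap(disjoint, R)$dice, 0)
  expect_error(areaOverlap(R, matrix(FALSE, 3, 3)), "empty")

  expect_identical(maskPrecision(R, R), 1)
  expect_equal(maskPrecision(T2, R2), 4 / 7, tolerance = 1e-15)
})

test_that("contour distances match exact geometry on concentric squares", {
  mk <- function(h) {
    m <- matrix(FALSE, 64, 64); m[(32 - h):(32 + h), (32 - h):(32 + h)] <- TRUE
    m
  }
  d <- contourDistances(mk(10), mk(12))
  expect_equal(d$msd, 2 * sqrt(2), tolerance = 1e-12)   # corner-to-corner
  expect_gte(d$asd, 2); expect_lte(d$asd, 2 * sqrt(2))

  same <- contourDistances(mk(10), mk(10))
  expect_identical(c(same$msd, same$asd, same$rmsd), c(0, 0, 0))

  # symmetry in the pair, and linear scaling with pixel spacing
  d2 <- contourDistances(mk(12), mk(10))
  expect_equal(d, d2, tolerance = 1e-12)
  d3 <- contourDistances(mk(10), mk(12), spacing = 0.2)
  expect_equal(d3$msd, d$msd * 0.2, tolerance = 1e-12)
  expect_equal(d3$asd, d$asd * 0.2, tolerance = 1e-12)
})

test_that("distance transform distances equal brute-force nearest neighbours", {
  set.seed(1)
  for (i in 1:5) {
    a <- matrix(runif(400) < 0.3, 20); b <- matrix(runif(400) < 0.3, 20)
    if (!any(a) || !any(b)) next
    d <- contourDistances(a, b)
    ba <- fcseg:::innerBoundary(a); bb <- fcseg:::innerBoundary(b)
    nn <- function(from, to) apply(from, 1, function(p)
      sqrt(min((to[, 1] - p[1])^2 + (to[, 2] - p[2])^2)))
    pool <- c(nn(ba, bb), nn(bb, ba))
    expect_equal(d$msd, max(pool), tolerance = 1e-9)
    expect_equal(d$asd, mean(pool), tolerance = 1e-9)
    expect_equal(d$rmsd, sqrt(mean(pool^2)), tolerance = 1e-9)
  }
})

test_that("power-mean ordering and translation invariance hold on random pairs", {
  set.seed(8)
  for (i in 1:10) {
    a <- matrix(FALSE, 40, 40); b <- matrix(FALSE, 40, 40)
    a[sample(1600, 200)] <- TRUE; b[sample(1600, 200)] <- TRUE
    d <- contourDistances(a, b)
    expect_lte(d$asd, d$rmsd + 1e-12)
    expect_lte(d$rmsd, d$msd + 1e-12)
  }
  a <- matrix(FALSE, 40, 40); a[10:20, 10:18] <- TRUE
  b <- matrix(FALSE, 40, 40); b[12:24, 8:20] <- TRUE
  sh <- function(m) rbind(matrix(FALSE, 5, 40), m[1:35, ])
  d0 <- contourDistances(a, b)
  d1 <- contourDistances(sh(a), sh(b))
  expect_equal(d0, d1, tolerance = 1e-12)
  ov0 <- areaOverlap(a, b); ov1 <- areaOverlap(sh(a), sh(b))
  expect_equal(ov0$dice, ov1$dice, tolerance = 1e-15)
})
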