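test_that("convex hull boundary covers all components and is closed", {
  sq <- matrix(FALSE, 40, 40); sq[10:30, 10:30] <- TRUE
  ch <- convexHullBoundary(sq)
  pts <- chainPoints(ch)
  expect_true(all(pts[, 1] >= 10 & pts[, 1] <= 30))
  expect_true(all(pts[, 2] >= 10 & pts[, 2] <= 30))
  # every chain point lies on the square's perimeter
  onEdge <- pts[, 1] %in% c(10, 30) | pts[, 2] %in% c(10, 30)
  expect_true(all(onEdge))

  # two disjoint blobs: one hull containing both
  two <- matrix(FALSE, 60, 60)
  two[10:18, 10:18] <- TRUE; two[40:50, 42:52] <- TRUE
  ch2 <- convexHullBoundary(two)
  fg <- which(two, arr.ind = TRUE)
  expect_true(all(fcseg:::pointInPolygon(fg[, 1], fg[, 2],
                                         chainPoints(ch2)) |
                  apply(fg, 1, function(p)
                    min(sqrt(rowSums(sweep(chainPoints(ch2), 2, p)^2))) < 1)))

  expect_error(convexHullBoundary(matrix(FALSE, 5, 5)), "empty")
  line <- matrix(FALSE, 10, 10); line[5, 2:8] <- TRUE
  expect_error(convexHullBoundary(line), "degenerate")
})

test_that("c-scale chord length follows circle sagitta geometry", {
  disk <- makeGapFixture(k = 0, rOuter = 50, rInner = 0, size = 128)
  ch <- cscaleChords(convexHullBoundary(disk), t = 5)
  expected <- 2 * sqrt(2 * 50 * 5 - 25)   # ~43.6 px
  frac <- mean(abs(chainChord(ch) - expected) <= 3)
  expect_gte(frac, 0.95)

  # straight boundary: the window grows until the corners stop it, so chords
  # on a long square side far exceed the circle chord at the same t
  sq <- matrix(FALSE, 140, 140); sq[20:120, 20:120] <- TRUE
  chs <- cscaleChords(convexHullBoundary(sq), t = 5)
  expect_gt(max(chainChord(chs)), 100)
})

test_that("inward normals point at the disk centre and into squares", {
  disk <- makeGapFixture(k = 0, rOuter = 50, rInner = 0, size = 128)
  ch <- inwardNormals(cscaleChords(convexHullBoundary(disk), 5))
  pts <- chainPoints(ch); nrm <- chainNormals(ch)
  ctr <- c(64.5, 64.5)
  outward <- sweep(pts, 2, ctr)
  outward <- outward / sqrt(rowSums(outward^2))
  cosang <- -rowSums(nrm * outward)
  expect_true(all(cosang > 0))                    # never outward
  expect_gt(mean(acos(pmin(1, cosang)) < 5 * pi / 180), 0.95)

  sq <- matrix(FALSE, 40, 40); sq[10:30, 10:30] <- TRUE
  chs <- inwardNormals(cscaleChords(convexHullBoundary(sq), 5))
  p <- chainPoints(chs); nn <- chainNormals(chs)
  mid <- which(p[, 1] == 10 & abs(p[, 2] - 20) < 1)[1]
  expect_equal(nn[mid, ], c(1, 0), tolerance = 1e-6)
})

test_that("thickness profile measures ring width and zeroes over wedges", {
  ann <- makeGapFixture(k = 0, rOuter = 60, rInner = 50, size = 150)
  ch <- thicknessProfile(inwardNormals(cscaleChords(convexHullBoundary(ann), 5)), ann)
  expect_true(all(abs(chainThickness(ch) - 10) <= 1.5))

  gap <- makeGapFixture(k = 1, wedgeDeg = 60)
  chg <- thicknessProfile(inwardNormals(cscaleChords(convexHullBoundary(gap), 5)), gap)
  expect_true(any(chainThickness(chg) == 0))

  disk <- makeGapFixture(k = 0, rOuter = 40, rInner = 0, size = 100)
  chd <- thicknessProfile(inwardNormals(cscaleChords(convexHullBoundary(disk), 5)), disk)
  expect_true(all(chainThickness(chd) > 0))
})

test_that("gap detection counts wedges exactly for k in 0..3", {
  for (k in 0:3) {
    m <- makeGapFixture(k = k, wedgeDeg = if (k < 3) 60 else 40)
    ch <- thicknessProfile(inwardNormals(cscaleChords(convexHullBoundary(m), 5)), m)
    gaps <- detectGaps(ch)
    expect_length(gaps, k)
  }
  expect_error(detectGaps(rep(0, 50)), "vanished")
  expect_length(detectGaps(c(rep(1, 10), 0, 0, rep(1, 10))), 0)  # below minLen
})

test_that("gap filling restores a closed ring and never removes pixels", {
  m <- makeGapFixture(k = 1, wedgeDeg = 60)
  ch <- thicknessProfile(inwardNormals(cscaleChords(convexHullBoundary(m), 5)), m)
  gaps <- detectGaps(ch)
  filled <- fillGaps(m, ch, gaps)
  expect_true(all(filled[m]))                       # superset
  topo <- fcseg:::maskTopology(filled)
  expect_identical(topo$components, 1L)
  expect_identical(topo$holes, 1L)

  expect_identical(fillGaps(m, ch, list()), m)      # zero gaps: identity
})

test_that("object completion is idempotent, superset-preserving and rotation-robust", {
  full <- makeGapFixture(k = 0)
  expect_identical(completeObject(full), full)      # closed ring: unchanged

  for (k in 1:3) {
    m <- makeGapFixture(k = k, wedgeDeg = 40)
    cm <- completeObject(m)
    expect_true(all(cm[m]))
    expect_identical(completeObject(cm), cm)
    topo <- fcseg:::maskTopology(cm)
    expect_identical(topo$components, 1L)
    expect_identical(topo$holes, 1L)
  }

  # two disjoint arcs become one connected ring
  arcs <- makeGapFixture(k = 2, wedgeDeg = 40)
  expect_identical(fcseg:::maskTopology(arcs)$components, 2L)
  expect_identical(fcseg:::maskTopology(completeObject(arcs))$components, 1L)

  # axis-aligned rotation: completion commutes with rot90 pixel-exactly
  m <- makeGapFixture(k = 1, wedgeDeg = 60)
  expect_identical(completeObject(rot90(m)), rot90(completeObject(m)))
})
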