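test_that("bandpass response is DC-free with the analytic peak frequency", {
  B <- makeBandpass(c(512, 512), bandpassSpec(27), normalise = FALSE)
  expect_identical(B[1, 1], 0)
  expect_true(all(B >= 0))
  u <- fcseg:::fftFreq(512)
  r <- sqrt(outer(u^2, u^2, "+"))
  # discrete argmax approaches the analytic peak 1/(sigma*sqrt(2))
  expect_equal(r[which.max(B)], 1 / (27 * sqrt(2)), tolerance = 2e-3)
  # larger sigma selects lower frequencies
  B23 <- makeBandpass(c(512, 512), 23, normalise = FALSE)
  expect_lt(r[which.max(B)], r[which.max(B23)])
  expect_error(makeBandpass(c(64, 64), bandpassSpec(-1)), "sigma")
})

test_that("Riesz responses annihilate constants and quadrature a pure cosine", {
  expect_true(all(abs(unlist(rieszResponses(matrix(5, 32, 32)))) < 1e-12))

  # cosine varying along columns: energy on the v axis only, so odd2 carries
  # the quadrature (sine) component and odd1 vanishes
  n <- 64; f <- 4 / n
  img <- matrix(cos(2 * pi * f * (0:(n - 1))), n, n, byrow = TRUE)
  rz <- rieszResponses(img)
  expect_lt(max(abs(rz$odd1)), 1e-9)
  expected <- matrix(sin(2 * pi * f * (0:(n - 1))), n, n, byrow = TRUE)
  expect_equal(rz$odd2, expected, tolerance = 1e-9, ignore_attr = TRUE)

  # |H1|^2 + |H2|^2 = 1 at every non-DC bin
  H <- fcseg:::rieszTransfer(c(16, 16))
  mag <- Mod(H$H1)^2 + Mod(H$H2)^2
  expect_equal(max(abs(mag[-1] - 1)), 0, tolerance = 1e-12)
  expect_identical(mag[1, 1], 0)
})

test_that("monogenic signal is linear and kills constant images", {
  const <- monogenicSignal(matrix(0.7, 48, 48), 10)
  expect_lt(max(abs(evenPart(const))), 1e-10)
  expect_lt(max(abs(oddParts(const)$odd1)), 1e-10)

  set.seed(42)
  img <- matrix(runif(48 * 48), 48, 48)
  m1 <- monogenicSignal(img, 10)
  m2 <- monogenicSignal(3 * img + 0.2, 10)
  expect_equal(evenPart(m2), 3 * evenPart(m1), tolerance = 1e-9)
  expect_equal(oddParts(m2)$odd2, 3 * oddParts(m1)$odd2, tolerance = 1e-9)

  expect_error(monogenicSignal(matrix(NA_real_, 4, 4), 10), "finite")
})

test_that("phantom amplitude at the ring scale peaks on the fat boundary", {
  ph <- defaultPhantom()
  A <- amplitudeMap(phaseMaps(monogenicSignal(ph$image, 27)))
  ctr <- (dim(A) + 1) / 2
  rows <- matrix(seq_len(nrow(A)), nrow(A), ncol(A))
  cols <- matrix(seq_len(ncol(A)), nrow(A), ncol(A), byrow = TRUE)
  rad <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  # outside the bone/shadow core, the strongest energy sits in the band the
  # fat-ring boundaries occupy (74..100 px), widened by the filter support
  Aout <- A; Aout[rad < 40] <- 0
  peakRad <- rad[which.max(Aout)]
  expect_gt(peakRad, 60)
  expect_lt(peakRad, 110)
  # and the ring band carries far more energy than the flat background
  expect_gt(mean(A[rad > 64 & rad < 110]), 3 * mean(A[rad > 115]))
})

test_that("phase maps satisfy the energy identity and contrast invariance", {
  set.seed(7)
  img <- matrix(runif(64 * 64), 64, 64)
  m <- monogenicSignal(img, 15)
  pm <- phaseMaps(m)
  odd <- oddParts(m)
  expect_equal(amplitudeMap(pm)^2,
               evenPart(m)^2 + odd$odd1^2 + odd$odd2^2, tolerance = 1e-12)
  expect_true(all(phaseMap(pm) >= 0 & phaseMap(pm) <= pi))

  pm2 <- phaseMaps(monogenicSignal(0.2 * img + 0.4, 15))
  expect_equal(phaseMap(pm2), phaseMap(pm), tolerance = 1e-9)
  expect_equal(orientationMap(pm2), orientationMap(pm), tolerance = 1e-9)
})

test_that("a step across columns has phase pi/2 and orientation 0 at the crest", {
  img <- stepImage(96)
  pm <- phaseMaps(monogenicSignal(img, 10))
  mid <- 48
  # the crest lies between the last low and first high column, so the two
  # samples bracket pi/2 and both sit within half a pixel's phase sweep
  expect_lt(abs(phaseMap(pm)[mid, 48] - pi / 2), 0.25)
  expect_lt(abs(phaseMap(pm)[mid, 49] - pi / 2), 0.25)
  expect_lt((phaseMap(pm)[mid, 48] - pi / 2) *
            (phaseMap(pm)[mid, 49] - pi / 2), 0)
  expect_lt(min(orientationMap(pm)[mid, 48],
                pi - orientationMap(pm)[mid, 48]), 0.05)
})

test_that("transposition rotates the orientation map consistently", {
  # transposing the image swaps the two Riesz axes, so orientation maps to
  # pi/2 - theta (mod pi) wherever the signal is strong
  img <- matrix(0, 80, 80)
  img[30:50, 20:60] <- 1
  img <- evenPart(monogenicSignal(img, 4)) + 0.5  # band-limited input
  pmA <- phaseMaps(monogenicSignal(img, 8))
  pmB <- phaseMaps(monogenicSignal(t(img), 8))
  strong <- amplitudeMap(pmA) > 0.25 * max(amplitudeMap(pmA))
  thA <- orientationMap(pmA)[strong]
  thB <- t(orientationMap(pmB))[strong]
  resid <- (thA + thB - pi / 2) %% pi
  dist0 <- pmin(resid, pi - resid)   # distance to 0 modulo pi
  expect_lt(stats::median(dist0), 0.05)
  expect_lt(mean(dist0 > 0.2), 0.05)
})
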