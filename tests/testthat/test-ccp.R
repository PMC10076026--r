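test_that("Sobel response: zero on constants, 4h on a step, isotropic", {
  mask <- matrix(TRUE, 30, 30)
  expect_true(all(sobelGradient(matrix(3, 30, 30), mask) == 0))

  h <- 0.7
  step <- matrix(0, 30, 30); step[, 16:30] <- h
  g <- sobelGradient(step, mask)
  expect_equal(max(g), 4 * h, tolerance = 1e-12)

  # rotated step: same peak magnitude within 5 %
  th <- 30 * pi / 180
  rot <- matrix(0, 60, 60)
  rot[(col(rot) - 30) * cos(th) + (row(rot) - 30) * sin(th) > 0] <- h
  rot <- nucmorph:::.gaussBlur(rot, 1)     # band-limit the diagonal edge
  stepS <- nucmorph:::.gaussBlur(step, 1)
  mask60 <- matrix(FALSE, 60, 60); mask60[10:50, 10:50] <- TRUE
  gR <- max(sobelGradient(rot, mask60))
  g0 <- max(sobelGradient(stepS, mask))
  expect_lt(abs(gR - g0) / g0, 0.05)
  expect_error(sobelGradient(step, mask & FALSE), "non-empty")
})

test_that("CCP equals the brute-force convolution oracle exactly", {
  for (s in 1:3) {
    ph <- makeNucleusPhantom(PhantomSpec(a = 4, b = 3,
                                         condensationLevel = 0.6, seed = s))
    m <- segmentNuclei(getChannel(ph$image, "DAPI"), 0.1)[[1]]
    res <- computeCCP(getChannel(ph$image, "DAPI"), m)
    oracle <- ccpOracle(getChannel(ph$image, "DAPI"), m@mask,
                        res@thresholdUsed)
    expect_equal(res@ccp, oracle, tolerance = 1e-14)
    expect_equal(res@ccp, res@edgePixelCount / res@areaPx)
    expect_true(all(m@mask[res@edgeMap]))
  }
})

test_that("uniform nucleus interior has CCP zero", {
  m <- matrix(FALSE, 40, 40); m[8:32, 8:32] <- TRUE
  res <- computeCCP(matrix(5, 40, 40), m)
  expect_equal(res@ccp, 0)
})

test_that("CCP increases with condensation level (pairwise and Spearman)", {
  ccpAt <- function(level, seed) {
    ph <- makeNucleusPhantom(PhantomSpec(condensationLevel = level,
                                         seed = seed))
    m <- segmentNuclei(getChannel(ph$image, "DAPI"), 0.1)[[1]]
    computeCCP(getChannel(ph$image, "DAPI"), m)@ccp
  }
  expect_gt(ccpAt(0.8, 5), ccpAt(0.2, 5))

  levels_ <- seq(0.1, 1, by = 0.1)
  vals <- vapply(levels_, ccpAt, numeric(1), seed = 17)
  expect_gte(cor(levels_, vals, method = "spearman"), 0.95)
})

test_that("CCP is invariant under affine rescaling with relative rules", {
  ph <- makeNucleusPhantom(PhantomSpec(condensationLevel = 0.5, seed = 2))
  m <- segmentNuclei(getChannel(ph$image, "DAPI"), 0.1)[[1]]
  d <- getChannel(ph$image, "DAPI")
  for (rule in c("otsu", "fraction")) {
    a <- computeCCP(d, m, rule)
    b <- computeCCP(2.5 * d + 3, m, rule)
    expect_identical(a@edgePixelCount, b@edgePixelCount)
  }
})

test_that("blurring suppresses edges at a fixed gradient cutoff", {
  for (s in 1:3) {
    ph <- makeNucleusPhantom(PhantomSpec(condensationLevel = 0.6, seed = s))
    m <- segmentNuclei(getChannel(ph$image, "DAPI"), 0.1)[[1]]
    d <- getChannel(ph$image, "DAPI")
    ref <- computeCCP(d, m, "otsu")
    blur <- computeCCP(nucmorph:::.gaussBlur(d, 2), m, "fixed",
                       fixedValue = ref@thresholdUsed)
    expect_lte(blur@ccp, ref@ccp)
  }
})
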