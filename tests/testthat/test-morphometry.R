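test_that("curvature of a circle is 1/r at every vertex", {
  prof <- curvatureProfile(circleContour(r = 10), smoothSigmaUm = 0)
  expect_lt(max(abs(prof@kappa - 0.1) / 0.1), 0.02)
  profS <- curvatureProfile(circleContour(r = 10), smoothSigmaUm = 0.4)
  expect_lt(max(abs(profS@kappa - 0.1) / 0.1), 0.02)
})

test_that("curvature at the major-axis endpoints of a 2:1 ellipse is a/b^2", {
  prof <- curvatureProfile(ellipseContour(a = 2, b = 1), smoothSigmaUm = 0)
  expect_lt(abs(max(prof@kappa) - 2) / 2, 0.03)
  expect_lt(abs(min(prof@kappa) - 0.25) / 0.25, 0.03)   # b/a^2 at minor axis
})

test_that("total turning is 2*pi on random lobed phantom contours", {
  set.seed(31)
  for (i in 1:20) {
    sp <- PhantomSpec(a = runif(1, 6, 9), b = runif(1, 4, 6),
                      nInvaginations = sample(0:3, 1),
                      invaginationDepth = runif(1, 0.15, 0.4),
                      seed = sample.int(1e6, 1))
    ph <- makeNucleusPhantom(sp)
    m <- segmentNuclei(getChannel(ph$image, "DAPI"), 0.1)[[1]]
    prof <- curvatureProfile(extractContour(m), 0.4)
    turning <- sum(prof@kappa) * prof@perimeterUm / length(prof@kappa)
    expect_lt(abs(turning - 2 * pi) / (2 * pi), 0.01)
  }
})

test_that("invagination calls recover lobe count and angular position", {
  prof0 <- curvatureProfile(ellipseContour(a = 8, b = 6), 0.4)
  call0 <- detectInvaginations(prof0)
  expect_false(call0@invaginated)
  expect_identical(nrow(call0@runs), 0L)

  for (k in c(1L, 3L)) {
    ph <- makeNucleusPhantom(PhantomSpec(nInvaginations = k,
                                         invaginationDepth = 0.3, seed = k))
    m <- segmentNuclei(getChannel(ph$image, "DAPI"), 0.1)[[1]]
    ct <- extractContour(m)
    call <- detectInvaginations(curvatureProfile(ct, 0.4))
    expect_true(call@invaginated)
    expect_identical(nrow(call@runs), as.integer(k))
    # each detected run sits within half a lobe width of a true lobe angle
    pts <- contourPoints(ct)
    cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
    n <- nrow(pts); h <- ct@spacingUm
    for (i in seq_len(nrow(call@runs))) {
      mid <- (call@runs$startUm[i] + call@runs$endUm[i]) / 2
      v <- pts[round(mid / h) %% n + 1, ]
      angle <- atan2(v[2] - cy, v[1] - cx)
      dAng <- abs(atan2(sin(angle - ph$truth$lobeThetas),
                        cos(angle - ph$truth$lobeThetas)))
      expect_lt(min(dAng), ph$truth$lobeWidth / 2)
    }
  }
})

test_that("invagination calling is invariant under physical rescaling", {
  ph <- makeNucleusPhantom(PhantomSpec(nInvaginations = 2L,
                                       invaginationDepth = 0.3, seed = 8))
  m <- segmentNuclei(getChannel(ph$image, "DAPI"), 0.1)[[1]]
  call1 <- detectInvaginations(curvatureProfile(extractContour(m), 0.4))
  # same shape imaged at half the magnification: scale the contour itself
  ct <- extractContour(m)
  ct2 <- Contour(contourPoints(ct) * 2, spacingUm = ct@spacingUm * 2)
  call2 <- detectInvaginations(curvatureProfile(ct2, 0.8))
  expect_identical(nrow(call1@runs), nrow(call2@runs))
})

test_that("wrinkle density is zero without ridges and tracks ground truth", {
  ph0 <- makeNucleusPhantom(PhantomSpec(nWrinkles = 0L))
  m0 <- segmentNuclei(getChannel(ph0$image, "DAPI"), 0.1)[[1]]
  wr0 <- wrinkleScore(getChannel(ph0$image, "lamin"), m0)
  expect_equal(wr0@ridgeLengthDensity, 0)
  expect_false(wr0@wrinkled)

  for (s in 2:4) {
    ph <- makeNucleusPhantom(PhantomSpec(nWrinkles = 3L, seed = s))
    m <- segmentNuclei(getChannel(ph$image, "DAPI"), 0.1)[[1]]
    wr <- wrinkleScore(getChannel(ph$image, "lamin"), m)
    gtDensity <- ph$truth$wrinkleLengthUm /
      (sum(ph$truth$wrinkleRegion) * 0.1^2)
    expect_lt(abs(wr@ridgeLengthDensity - gtDensity) / gtDensity, 0.2)
    expect_true(wr@wrinkled)
  }
})

test_that("wrinkle density increases strictly with ridge count", {
  dens <- vapply(0:5, function(k) {
    ph <- makeNucleusPhantom(PhantomSpec(nWrinkles = as.integer(k), seed = 11))
    m <- segmentNuclei(getChannel(ph$image, "DAPI"), 0.1)[[1]]
    wrinkleScore(getChannel(ph$image, "lamin"), m)@ridgeLengthDensity
  }, numeric(1))
  expect_true(all(diff(dens) > 0))
})

test_that("voxelised ellipsoid recovers analytic volume, area and height", {
  ph <- makeNucleusPhantom(PhantomSpec(a = 5, b = 4, c = 3,
                                       pixelSizeUm = 0.2, zStepUm = 0.2))
  geo <- nucleusGeometry(ph$truth$mask3d, 0.2, 0.2)
  expect_lt(abs(geo["volumeUm3"] - 4 / 3 * pi * 60) / (4 / 3 * pi * 60), 0.02)
  expect_lt(abs(geo["areaUm2"] - 20 * pi) / (20 * pi), 0.02)
  expect_lte(abs(geo["heightUm"] - 6), 0.2)   # within one z-step
  expect_error(nucleusGeometry(array(FALSE, c(4, 4, 4)), 0.2, 0.2), "empty")
})

test_that("shape descriptors: disk, 2:1 ellipse, rotation equivariance", {
  disk <- matrix(FALSE, 101, 101)
  disk[(row(disk) - 51)^2 + (col(disk) - 51)^2 <= 40^2] <- TRUE
  sd0 <- shapeDescriptors(disk, 1)
  expect_lt(abs(sd0["aspectRatio"] - 1), 0.02)

  mkEll <- function(theta) {
    m <- matrix(FALSE, 201, 201)
    y <- row(m) - 101; x <- col(m) - 101
    xr <- x * cos(theta) + y * sin(theta)
    yr <- -x * sin(theta) + y * cos(theta)
    m[(xr / 80)^2 + (yr / 40)^2 <= 1] <- TRUE
    m
  }
  s0 <- shapeDescriptors(mkEll(0), 1)
  expect_lt(abs(s0["aspectRatio"] - 2) / 2, 0.03)
  expect_lt(abs(s0["orientationDeg"]), 2)
  s30 <- shapeDescriptors(mkEll(30 * pi / 180), 1)
  expect_lt(abs(abs(s30["orientationDeg"]) - 30), 2)
  expect_lt(abs(s30["areaUm2"] - s0["areaUm2"]) / s0["areaUm2"], 0.01)
})

test_that("mean intensity, background subtraction and ratios are exact", {
  m <- matrix(TRUE, 10, 10)
  expect_equal(meanIntensity(matrix(7, 10, 10), m), 7)
  half <- matrix(c(rep(0, 50), rep(10, 50)), 10, 10)
  expect_equal(meanIntensity(half, m), 5)
  img <- matrix(2, 20, 20); inner <- matrix(FALSE, 20, 20)
  inner[8:13, 8:13] <- TRUE; img[inner] <- 7
  expect_equal(meanIntensity(img, inner, backgroundSubtract = TRUE), 5,
               tolerance = 0.05)

  cellM <- matrix(TRUE, 10, 10)
  nucM <- matrix(FALSE, 10, 10); nucM[3:7, 3:7] <- TRUE
  chan <- matrix(100, 10, 10); chan[nucM] <- 200
  expect_equal(nucleocytoplasmicRatio(chan, nucM, cellM), 2)
  expect_equal(nucleocytoplasmicRatio(matrix(5, 10, 10), nucM, cellM), 1)
  expect_error(nucleocytoplasmicRatio(chan, cellM, cellM), "empty")
})

test_that("nucleocytoplasmic ratio recovers the generated enrichment", {
  ph <- makeNucleusPhantom(PhantomSpec(ncEnrichment = 3,
                                       noiseGaussianSd = 0.01,
                                       noisePoissonGain = 500, seed = 6))
  m <- segmentNuclei(getChannel(ph$image, "DAPI"), 0.1)[[1]]
  r <- nucleocytoplasmicRatio(getChannel(ph$image, "marker"), m@mask,
                              ph$truth$cellMask | m@mask)
  expect_lt(abs(r - 3) / 3, 0.05)
})

test_that("positive fraction is the strict exceedance fraction", {
  expect_equal(positiveFraction(c(1, 2, 3, 4), 2.5), 0.5)
  expect_equal(positiveFraction(c(1, 2), 10), 0)
  expect_equal(positiveFraction(c(1, 2), 0), 1)
  expect_error(positiveFraction(numeric(0), 1), "empty")
})
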