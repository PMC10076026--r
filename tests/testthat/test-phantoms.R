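test_that("phantom generation is bit-identical under a fixed seed", {
  sp <- PhantomSpec(nInvaginations = 2L, nWrinkles = 2L,
                    condensationLevel = 0.5, noiseGaussianSd = 0.02,
                    noisePoissonGain = 200, seed = 99L)
  a <- makeNucleusPhantom(sp)
  b <- makeNucleusPhantom(sp)
  expect_identical(a$image@pixels, b$image@pixels)
  expect_identical(a$truth$lobeThetas, b$truth$lobeThetas)
})

test_that("lobe-free phantoms are convex; analytic arc count equals lobes", {
  ph0 <- makeNucleusPhantom(PhantomSpec(nInvaginations = 0L))
  expect_true(all(ph0$truth$kappaTrue > 0))
  expect_identical(ph0$truth$negativeArcCount, 0L)

  for (k in 1:3) {
    ph <- makeNucleusPhantom(PhantomSpec(nInvaginations = as.integer(k),
                                         invaginationDepth = 0.3, seed = k))
    expect_identical(ph$truth$negativeArcCount, as.integer(k))
  }
})

test_that("overlapping or pinching lobes are rejected", {
  expect_error(PhantomSpec(nInvaginations = 6L, invaginationWidth = 1.1),
               "overlap")
  expect_error(
    makeNucleusPhantom(PhantomSpec(nInvaginations = 1L,
                                   invaginationDepth = 0.95)),
    "pinch")
  expect_error(PhantomSpec(nInvaginations = 1L, invaginationDepth = 1.2),
               "invaginationDepth")
})

test_that("condensation texture: level 0 uniform, foci confined, edges grow", {
  region <- matrix(FALSE, 60, 60); region[10:50, 10:50] <- TRUE
  expect_true(all(makeCondensationTexture(0, region) == 0))
  expect_error(makeCondensationTexture(0.5, region & FALSE), "empty region")
  tex <- makeCondensationTexture(0.7, region, seed = 4)
  expect_true(all(tex[!region] == 0))
  # edge density, by the package's own Sobel operator at a common absolute
  # cutoff, grows with level
  base <- matrix(0, 60, 60); base[region] <- 0.5
  lo <- computeCCP(base + makeCondensationTexture(0.2, region, seed = 4),
                   region, "fixed", fixedValue = 0.3)
  hi <- computeCCP(base + makeCondensationTexture(0.8, region, seed = 4),
                   region, "fixed", fixedValue = 0.3)
  expect_gt(hi@edgePixelCount, lo@edgePixelCount)
})

test_that("cohort prevalences are honoured within binomial bounds", {
  co <- makeCohort(list(ctrl = list(pInvaginated = 1, pWrinkled = 0, n = 10)),
                   nReplicates = 1L, seed = 5)
  expect_length(co, 10L)
  expect_true(all(vapply(co, function(e) e$truth$invaginated, TRUE)))
  expect_false(any(vapply(co, function(e) e$truth$wrinkled, TRUE)))

  co2 <- makeCohort(list(b = list(pInvaginated = 0.85, pWrinkled = 0, n = 50)),
                    nReplicates = 3L, seed = 11)
  frac <- mean(vapply(co2, function(e) e$truth$invaginated, TRUE))
  # 99% binomial interval around 0.85 at n = 150
  expect_lt(abs(frac - 0.85), 2.58 * sqrt(0.85 * 0.15 / 150))

  co3 <- makeCohort(list(b = list(pInvaginated = 0.85, pWrinkled = 0, n = 5)),
                    nReplicates = 1L, seed = 11)
  expect_identical(vapply(co3, function(e) e$truth$invaginated, TRUE),
                   vapply(makeCohort(list(b = list(pInvaginated = 0.85,
                                                   pWrinkled = 0, n = 5)),
                                     nReplicates = 1L, seed = 11),
                          function(e) e$truth$invaginated, TRUE))
})

test_that("TFM pair: zero traction leaves beads in place", {
  gel <- GelModel(15000, 0.5)
  pair <- makeTfmPair(noPatches(), gel, fieldSizePx = 64L, seed = 2)
  expect_identical(pair$reference, pair$displaced)
  expect_equal(max(abs(pair$tractionTrue@tx)), 0)
})

test_that("TFM pair: linear elasticity halves displacement when E doubles", {
  p1 <- makeTfmPair(dipolePatches(64, sigmaUm = 8), GelModel(15000, 0.5),
                    fieldSizePx = 128L, seed = 2)
  p2 <- makeTfmPair(dipolePatches(64, sigmaUm = 8), GelModel(30000, 0.5),
                    fieldSizePx = 128L, seed = 2)
  expect_equal(p1$displacementTrue@ux, 2 * p2$displacementTrue@ux,
               tolerance = 1e-12)
})

test_that("TFM pair: dipole forcing has zero mean displacement and force", {
  pair <- makeTfmPair(dipolePatches(64, sigmaUm = 8), GelModel(15000, 0.5),
                      fieldSizePx = 128L, seed = 2)
  expect_lt(abs(mean(pair$tractionTrue@tx)), 1e-12)
  expect_lt(abs(mean(pair$displacementTrue@ux)),
            1e-9 * max(abs(pair$displacementTrue@ux)))
  expect_error(
    makeTfmPair(data.frame(xUm = 16, yUm = 16, sigmaUm = 20, txPa = 100,
                           tyPa = 0), GelModel(15000), fieldSizePx = 64L),
    "wider than the field")
})
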