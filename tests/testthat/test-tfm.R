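test_that("drift alignment recovers constructed shifts", {
  pair <- makeTfmPair(noPatches(), GelModel(15000), fieldSizePx = 256L,
                      beadDensity = 0.02, seed = 7)
  img <- pair$reference
  # integer shift via circular roll
  roll <- function(m, dy, dx) {
    n1 <- nrow(m); n2 <- ncol(m)
    m[((seq_len(n1) - 1 - dy) %% n1) + 1, ((seq_len(n2) - 1 - dx) %% n2) + 1]
  }
  a <- alignDrift(img, roll(img, -2, 3))
  expect_equal(unname(a$shift), c(3, -2), tolerance = 0.01)
  b <- alignDrift(img, img)
  expect_equal(unname(b$shift), c(0, 0), tolerance = 1e-9)
  # subpixel shift via bilinear resampling of the rendered beads
  yy <- matrix(seq_len(256), 256, 256); xx <- t(yy)
  moved <- matrix(nucmorph:::.bilinear(img, yy - 0.25, xx - 0.5), 256, 256)
  d <- alignDrift(img, moved)
  expect_lt(max(abs(unname(d$shift) - c(0.5, 0.25))), 0.1)
  expect_warning(alignDrift(matrix(0, 32, 32), matrix(0, 32, 32)), "quality")
})

test_that("PIV recovers uniform shifts and returns zero on identity", {
  pair <- makeTfmPair(noPatches(), GelModel(15000), fieldSizePx = 320L,
                      beadDensity = 0.02, seed = 7)
  big <- pair$reference
  ref <- big[11:274, 11:274]
  mov <- big[8:271, 9:272]                 # mov(x) = ref(x - (3, 2))
  pv <- pivDisplacement(ref, mov, windowPx = 32L, overlapFrac = 0.5)
  expect_lt(max(abs(pv@ux - 2), abs(pv@uy - 3)), 1e-9)   # exact recovery

  pv0 <- pivDisplacement(ref, ref, windowPx = 32L)
  expect_lt(max(abs(pv0@ux), abs(pv0@uy)), 1e-9)
  expect_error(pivDisplacement(ref, mov, windowPx = 512L), "window")
})

test_that("PIV tracks a linear shear field to < 0.1 px RMS", {
  set.seed(7)
  n <- 264L
  nb <- round(0.02 * n * n)                # bead density 0.02 / px^2
  bx <- runif(nb, 5, n - 4); by <- runif(nb, 5, n - 4)
  gamma <- 0.015                           # du_x/dy, px per px
  ref <- renderBeads(bx, by, n)
  mov <- renderBeads(bx + gamma * (by - n / 2), by, n)
  pv <- pivDisplacement(ref, mov, windowPx = 32L, overlapFrac = 0.5)
  uxT <- matrix(gamma * (pv@y - n / 2), length(pv@y), length(pv@x))
  rms <- sqrt(mean((pv@ux - uxT)^2 + pv@uy^2))
  expect_lt(rms, 0.1)
})

test_that("FTTC: zero displacement, exact round trip, zero net force", {
  gel <- GelModel(15000, 0.5)
  pair <- makeTfmPair(dipolePatches(128), gel, fieldSizePx = 256L,
                      pixelSizeUm = 0.5, beadDensity = 0.01, seed = 3)
  zero <- subsampleField(pair$displacementTrue, 4)
  zero@ux[] <- 0; zero@uy[] <- 0
  tz <- fttcTraction(zero, gel, 0)
  expect_equal(max(abs(tz@tx), abs(tz@ty)), 0)

  df <- subsampleField(pair$displacementTrue, 4)
  tf <- fttcTraction(df, gel, 0)
  idx <- seq(4, 256, by = 4)
  txT <- pair$tractionTrue@tx[idx, idx]; tyT <- pair$tractionTrue@ty[idx, idx]
  rel <- sqrt(sum((tf@tx - txT)^2 + (tf@ty - tyT)^2) / sum(txT^2 + tyT^2))
  expect_lt(rel, 0.10)
  expect_lte(sqrt(mean(tf@tx)^2 + mean(tf@ty)^2),
             1e-6 * max(sqrt(tf@tx^2 + tf@ty^2)))
  expect_error(fttcTraction(df, gel, -1), "lambda")
})

test_that("FTTC is linear in u, scales with E, and shrinks with lambda", {
  gel <- GelModel(15000, 0.5)
  pair <- makeTfmPair(dipolePatches(128), gel, fieldSizePx = 256L,
                      pixelSizeUm = 0.5, beadDensity = 0.01, seed = 3)
  df <- subsampleField(pair$displacementTrue, 4)
  t1 <- fttcTraction(df, gel, 0)
  df2 <- df; df2@ux <- 3 * df@ux; df2@uy <- 3 * df@uy
  t3 <- fttcTraction(df2, gel, 0)
  expect_lt(max(abs(t3@tx - 3 * t1@tx)), 1e-6 * max(abs(t1@tx)))
  tE <- fttcTraction(df, GelModel(30000, 0.5), 0)
  expect_lt(max(abs(tE@tx - 2 * t1@tx)), 1e-6 * max(abs(t1@tx)))

  set.seed(5)
  dfn <- subsampleField(pair$displacementTrue, 4, noiseSd = 0.02)
  norms <- vapply(10^seq(-8, -2, by = 1), function(l) {
    t <- fttcTraction(dfn, gel, l)
    sqrt(sum(t@tx^2 + t@ty^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-9))
})

test_that("noisy displacements with GCV-selected lambda reconstruct <= 25%", {
  gel <- GelModel(15000, 0.5)
  pair <- makeTfmPair(dipolePatches(128, sigmaUm = 12, tPa = 2000), gel,
                      fieldSizePx = 256L, pixelSizeUm = 0.5,
                      beadDensity = 0.01, seed = 3)
  set.seed(9)
  df <- subsampleField(pair$displacementTrue, 8, noiseSd = 0.05 * 0.5)
  tf <- fttcTraction(df, gel, "gcv")
  idx <- seq(8, 256, by = 8)
  txT <- pair$tractionTrue@tx[idx, idx]; tyT <- pair$tractionTrue@ty[idx, idx]
  rel <- sqrt(sum((tf@tx - txT)^2 + (tf@ty - tyT)^2) / sum(txT^2 + tyT^2))
  expect_lt(rel, 0.25)
  expect_gt(tf@lambda, 0)
})

test_that("mean traction: constants, zero fields and the round trip", {
  grid <- seq(0, 31) * 1.0
  # constant |T| = 100 Pa with vanishing net force: two opposed blocks
  tx <- matrix(60, 32, 32); tx[, 17:32] <- -60
  ty <- matrix(80, 32, 32); ty[, 17:32] <- -80
  tfB <- new("TractionField", x = grid, y = grid, tx = tx, ty = ty,
             lambda = 0)
  expect_equal(meanTraction(tfB), 100)
  tz <- new("TractionField", x = grid, y = grid, tx = matrix(0, 32, 32),
            ty = matrix(0, 32, 32), lambda = 0)
  expect_equal(meanTraction(tz), 0)

  gel <- GelModel(15000, 0.5)
  pair <- makeTfmPair(dipolePatches(128), gel, fieldSizePx = 256L,
                      pixelSizeUm = 0.5, beadDensity = 0.01, seed = 3)
  df <- subsampleField(pair$displacementTrue, 4)
  tf <- fttcTraction(df, gel, 0)
  idx <- seq(4, 256, by = 4)
  mTrue <- mean(sqrt(pair$tractionTrue@tx[idx, idx]^2 +
                       pair$tractionTrue@ty[idx, idx]^2))
  expect_lt(abs(meanTraction(tf) - mTrue) / mTrue, 0.15)
  mask <- matrix(FALSE, 256, 256)
  expect_error(meanTraction(tf, mask, 0.5), "overlap")
})
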