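test_that("TIFF write-then-read round-trips pixels and calibration", {
  arr <- array(runif(32 * 40 * 2 * 3), dim = c(32, 40, 2, 3))
  img <- new("ImageStack", pixels = arr, channelNames = c("DAPI", "lamin"),
             pixelSizeUm = 0.2, zStepUm = 0.5)
  path <- tempfile(fileext = ".tif")
  writeImage(img, path)
  back <- readImageScaled(path)
  expect_equal(back@pixels, arr, tolerance = 1e-6)   # 32-bit float storage
  expect_identical(channelNames(back), c("DAPI", "lamin"))
  expect_equal(pixelSize(back), 0.2)
  expect_equal(zStep(back), 0.5)
  expect_true(isStack3D(back))
})

test_that("missing calibration falls back to 1 um/px with a warning", {
  m <- matrix(runif(64), 8, 8)
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(m, path, bits.per.sample = 32L)    # no metadata sidecar
  expect_warning(img <- readImage(path), "1\\.0 um/pixel")
  expect_equal(pixelSize(img), 1.0)
  expect_equal(getChannel(img), m, tolerance = 1e-6)
})

test_that("unreadable paths and zero-size images raise informative errors", {
  expect_error(readImage("/nonexistent/img.tif"), "no such file")
  bad <- tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(readImage(bad), "failed to read TIFF")
})

test_that("ImageStack validity rejects bad pixels and calibration", {
  expect_error(ImageStack(matrix(-1, 4, 4)), "0")
  expect_error(ImageStack(matrix(NA_real_, 4, 4)), "finite")
  expect_error(ImageStack(matrix(1, 4, 4), pixelSizeUm = 0), "positive")
  expect_error(ImageStack(array(1, c(4, 4, 2, 1)), channelNames = "one"),
               "channel")
})

test_that("record CSV round-trips values at full precision", {
  recs <- list(list(label = 1L, areaUm2 = 123.456789012345, invaginated = TRUE),
               list(label = 2L, areaUm2 = pi, invaginated = FALSE))
  path <- tempfile(fileext = ".csv")
  writeRecords(recs, path)
  lines <- readLines(path)
  expect_length(lines, 3L)                 # header + 2 rows
  back <- readRecords(path)
  expect_equal(back$areaUm2, c(123.456789012345, pi))
  expect_equal(back$invaginated, c(TRUE, FALSE))

  writeRecords(list(), path)
  expect_length(readLines(path), 1L)       # header-only for an empty list
})

test_that("run config merges over defaults and rejects unknown keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("curvature:", "  smoothSigmaUm: 0.8", "seed: 7"), path)
  cfg <- readRunConfig(path)
  expect_equal(cfg$curvature$smoothSigmaUm, 0.8)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$invagination$lenMinFrac,
               defaultRunConfig()$invagination$lenMinFrac)
  writeLines(c("curvture:", "  smoothSigmaUm: 0.8"), path)   # typo
  expect_error(readRunConfig(path), "unknown config key")
})
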