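# Calibrated TIFF input/output and tabular result output.
#
# Calibration: readImage() first looks for TIFF resolution tags
# (x.resolution + resolution.unit, as written e.g. by ImageJ), then for a
# JSON sidecar "<path>.meta.json" (written by writeImage(); the baseline
# TIFF writer used here cannot embed resolution tags), and finally falls
# back to 1.0 um/pixel with a warning -- phantoms are self-calibrated, so a
# hard failure would be worse than a flagged default.

#' Read a calibrated TIFF / OME-TIFF image
#'
#' Planes are normalised to the package's canonical axis order
#' \code{(y, x, channel, z)}. Multi-page files are interpreted using the
#' sidecar metadata when present (\code{nChannels}, \code{nz}); otherwise
#' every page is treated as a z-plane of a single channel.
#'
#' @param path path to a TIFF file.
#' @return An \linkS4class{ImageStack}; missing calibration falls back to
#'   1.0 um/pixel with a warning.
#' @export
readImage <- function(path) {
  .assert(file.exists(path), sprintf("cannot read image: no such file '%s'", path))
  planes <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                     error = function(e)
                       stop(sprintf("failed to read TIFF '%s': %s", path,
                                    conditionMessage(e)), call. = FALSE))
  if (!is.list(planes)) planes <- list(planes)
  .assert(length(planes) > 0 && length(dim(planes[[1]])) >= 2 &&
            all(dim(planes[[1]])[1:2] > 0), "zero-size image")

  meta <- NULL
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  pixelSizeUm <- NA_real_
  xres <- attr(planes[[1]], "x.resolution")
  unit <- attr(planes[[1]], "resolution.unit")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    umPerUnit <- switch(if (is.null(unit)) "inch" else unit,
                        inch = 25400, cm = 10000, 25400)
    pixelSizeUm <- umPerUnit / xres
  }
  if (is.na(pixelSizeUm) && !is.null(meta$pixelSizeUm))
    pixelSizeUm <- as.numeric(meta$pixelSizeUm)
  if (is.na(pixelSizeUm)) {
    warning(sprintf("'%s' carries no pixel-size calibration; using 1.0 um/pixel",
                    path))
    pixelSizeUm <- 1.0
  }

  nCh <- if (!is.null(meta$nChannels)) as.integer(meta$nChannels) else 1L
  # a single RGB/multi-sample page: samples become channels
  if (length(planes) == 1L && length(dim(planes[[1]])) == 3L) {
    a <- planes[[1]]
    nCh <- dim(a)[3]
    pix <- array(a, dim = c(dim(a)[1:2], nCh, 1L))
  } else {
    nz <- length(planes) %/% nCh
    .assert(nz * nCh == length(planes),
            "page count is not a multiple of the channel count")
    d <- dim(planes[[1]])[1:2]
    pix <- array(0, dim = c(d[1], d[2], nCh, nz))
    # page order: channel fastest, then z (as written by writeImage)
    k <- 1L
    for (z in seq_len(nz)) for (ch in seq_len(nCh)) {
      pix[, , ch, z] <- planes[[k]][, , drop = TRUE][seq_len(d[1]), seq_len(d[2])]
      k <- k + 1L
    }
  }
  chn <- if (!is.null(meta$channelNames)) as.character(meta$channelNames)
         else paste0("ch", seq_len(dim(pix)[3]))
  zs <- if (!is.null(meta$zStepUm)) as.numeric(meta$zStepUm)
        else if (dim(pix)[4] > 1L) 1.0 else NA_real_
  new("ImageStack", pixels = pix, channelNames = chn,
      pixelSizeUm = pixelSizeUm, zStepUm = zs)
}

#' Write an ImageStack as a multi-page 32-bit float TIFF
#'
#' Intensities are scaled into [0, 1] for storage (the scale factor is
#' recorded in the sidecar and undone on read). A JSON sidecar
#' \code{<path>.meta.json} carries pixel size, z-step, channel names and
#' page layout so that \code{readImage(writeImage(x))} reproduces pixels
#' and calibration.
#'
#' @param img an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeImage <- function(img, path) {
  .assert(is(img, "ImageStack"), "img must be an ImageStack")
  pix <- img@pixels
  sc <- max(pix)
  if (sc <= 0) sc <- 1
  pages <- list()
  k <- 1L
  for (z in seq_len(dim(pix)[4])) for (ch in seq_len(dim(pix)[3])) {
    pages[[k]] <- pix[, , ch, z] / sc
    k <- k + 1L
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 32L),
                 error = function(e)
                   stop(sprintf("cannot write TIFF '%s': %s", path,
                                conditionMessage(e)), call. = FALSE))
  meta <- list(pixelSizeUm = img@pixelSizeUm, zStepUm = img@zStepUm,
               channelNames = img@channelNames,
               nChannels = dim(pix)[3], nz = dim(pix)[4],
               intensityScale = sc)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# undo the storage scale on read, when a sidecar is present
.applyScale <- function(img, path) {
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$intensityScale))
      img@pixels <- img@pixels * as.numeric(meta$intensityScale)
  }
  img
}

#' Read an image written by writeImage, restoring the intensity scale
#'
#' @inheritParams readImage
#' @return An \linkS4class{ImageStack}.
#' @export
readImageScaled <- function(path) .applyScale(readImage(path), path)

#' Write per-nucleus measurement records to CSV
#'
#' One row per nucleus, stable column order (that of the first record),
#' full floating-point precision.
#'
#' @param records a data.frame, or a list of named lists sharing a schema.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRecords <- function(records, path) {
  if (is.data.frame(records)) df <- records
  else if (length(records) == 0L) df <- data.frame()
  else {
    nms <- names(records[[1]])
    .assert(all(vapply(records, function(r) identical(names(r), nms), TRUE)),
            "records do not share a schema")
    df <- do.call(rbind, lapply(records, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement CSV written by writeRecords
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readRecords <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default run configuration
#'
#' Every tunable parameter of the pipeline with its documented default.
#' Units: sigmas and lengths in micrometres unless suffixed \code{Px}.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    channels = list(dapi = "DAPI", shell = "lamin"),
    segmentation = list(smoothSigmaPx = 1, minAreaPx = 200,
                        excludeBorder = TRUE),
    contour = list(smoothSigmaPx = 1, spacingFactor = 0.5),
    curvature = list(smoothSigmaUm = 0.4),
    invagination = list(kappaMinFactor = 0.25, lenMinFrac = 0.02),
    wrinkle = list(scaleUm = 0.25, marginUm = 1.0, highThreshold = 1.0,
                   lowThreshold = 0.4, densityMin = 0.02),
    ccp = list(thresholdRule = "otsu", fixedFraction = 0.25),
    tfm = list(windowPx = 32, overlapFrac = 0.5, lambda = 0,
               nu = 0.5, window = "none"),
    seed = 1L
  )
}

#' Read a YAML run configuration
#'
#' Values are merged over \code{\link{defaultRunConfig}}; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return nested named list with all parameters populated.
#' @export
readRunConfig <- function(path) {
  .assert(file.exists(path), sprintf("no such config file '%s'", path))
  user <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  checkKeys <- function(u, d, prefix = "") {
    bad <- setdiff(names(u), names(d))
    .assert(length(bad) == 0L,
            sprintf("unknown config key(s): %s",
                    paste0(prefix, bad, collapse = ", ")))
    for (k in names(u)) if (is.list(d[[k]]) && is.list(u[[k]]))
      checkKeys(u[[k]], d[[k]], paste0(prefix, k, "."))
  }
  if (length(user)) checkKeys(user, def)
  modifyList(def, if (length(user)) user else list())
}
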