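# End-to-end per-nucleus measurement: the glue that the cohort analyses
# and the benchmark scripts drive.

#' Measure every nucleus in an image
#'
#' Segments the DAPI channel, then per nucleus: extracts the subpixel
#' contour, profiles curvature, calls invaginations, scores wrinkles on
#' the shell channel (DAPI if no shell channel exists), computes shape
#' descriptors, mean channel intensities and the CCP. One row per nucleus.
#'
#' @param img an \linkS4class{ImageStack} (2D; use the projection of a
#'   stack for detection).
#' @param config nested parameter list, see \code{\link{defaultRunConfig}}.
#' @return data.frame with one row per nucleus: \code{label},
#'   \code{invaginated}, \code{nInvaginations}, \code{wrinkled},
#'   \code{ridgeLengthDensity}, \code{areaUm2}, \code{aspectRatio},
#'   \code{orientationDeg}, \code{ccp}, and \code{meanIntensity.<channel>}
#'   columns.
#' @export
measureNuclei <- function(img, config = defaultRunConfig()) {
  .assert(is(img, "ImageStack"), "img must be an ImageStack")
  dapiName <- config$channels$dapi
  dapiIdx <- if (dapiName %in% channelNames(img)) dapiName else 1L
  dapi <- getChannel(img, dapiIdx, if (isStack3D(img)) "max" else 1L)
  shellName <- config$channels$shell
  shell <- if (shellName %in% channelNames(img))
    getChannel(img, shellName, 1L) else dapi
  masks <- segmentNuclei(dapi, pixelSizeUm = pixelSize(img),
                         smoothSigmaPx = config$segmentation$smoothSigmaPx,
                         minAreaPx = config$segmentation$minAreaPx,
                         excludeBorder = config$segmentation$excludeBorder)
  if (length(masks) == 0L) return(data.frame())
  rows <- lapply(masks, function(nm) {
    ct <- extractContour(nm, smoothSigmaPx = config$contour$smoothSigmaPx,
                         spacingFactor = config$contour$spacingFactor)
    prof <- curvatureProfile(ct, config$curvature$smoothSigmaUm)
    inv <- detectInvaginations(prof,
                               kappaMinFactor = config$invagination$kappaMinFactor,
                               lenMinFrac = config$invagination$lenMinFrac)
    wr <- wrinkleScore(shell, nm, scaleUm = config$wrinkle$scaleUm,
                       marginUm = config$wrinkle$marginUm,
                       highThreshold = config$wrinkle$highThreshold,
                       lowThreshold = config$wrinkle$lowThreshold,
                       densityMin = config$wrinkle$densityMin)
    sh <- shapeDescriptors(nm)
    cc <- computeCCP(dapi, nm, thresholdRule = config$ccp$thresholdRule,
                     fixedFraction = config$ccp$fixedFraction)
    row <- data.frame(label = nm@label,
                      invaginated = inv@invaginated,
                      nInvaginations = nrow(inv@runs),
                      wrinkled = wr@wrinkled,
                      ridgeLengthDensity = wr@ridgeLengthDensity,
                      areaUm2 = unname(sh["areaUm2"]),
                      aspectRatio = unname(sh["aspectRatio"]),
                      orientationDeg = unname(sh["orientationDeg"]),
                      ccp = cc@ccp)
    for (ch in channelNames(img))
      row[[paste0("meanIntensity.", ch)]] <-
        meanIntensity(getChannel(img, ch, 1L), nm)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Measure a phantom cohort and attach condition labels
#'
#' Runs \code{\link{measureNuclei}} over the output of
#' \code{\link{makeCohort}} and binds condition/replicate labels, ready
#' for \code{\link{conditionFractions}} and \code{\link{anovaTukey}}.
#'
#' @param cohort list from \code{\link{makeCohort}}.
#' @param config parameter list, see \code{\link{defaultRunConfig}}.
#' @return data.frame of per-nucleus records with \code{condition},
#'   \code{replicate} and ground-truth columns \code{trueInvaginated},
#'   \code{trueWrinkled} appended.
#' @export
analyzeCohort <- function(cohort, config = defaultRunConfig()) {
  rows <- lapply(cohort, function(entry) {
    rec <- measureNuclei(entry$image, config)
    if (nrow(rec) == 0L) return(NULL)
    rec <- rec[1, , drop = FALSE]            # one phantom nucleus per image
    rec$condition <- entry$condition
    rec$replicate <- entry$replicate
    rec$trueInvaginated <- entry$truth$invaginated
    rec$trueWrinkled <- entry$truth$wrinkled
    rec
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
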