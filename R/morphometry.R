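# Curvature profiling, invagination calling, wrinkle scoring, 3D geometry
# and intensity readouts.

#' Signed curvature along a closed contour
#'
#' Contour coordinates are smoothed by a periodic Gaussian of physical
#' scale \code{smoothSigmaUm}, then
#' \deqn{\kappa = (x' y'' - y' x'') / (x'^2 + y'^2)^{3/2}}
#' is evaluated by central differences on the uniform arc-length
#' parameterisation. Under the counterclockwise convention positive
#' \eqn{\kappa} is locally convex (outward-bulging), so invaginations are
#' negative-curvature arcs. The discrete total turning
#' \eqn{\sum \kappa \Delta s} equals \eqn{2\pi} to within a percent for any
#' simple contour.
#'
#' @param contour a \linkS4class{Contour}.
#' @param smoothSigmaUm Gaussian smoothing scale in micrometres
#'   (default 0.4); 0 disables smoothing.
#' @return a \linkS4class{CurvatureProfile}.
#' @export
curvatureProfile <- function(contour, smoothSigmaUm = 0.4) {
  .assert(is(contour, "Contour"), "contour must be a Contour")
  .assert(smoothSigmaUm >= 0, "smoothSigmaUm must be >= 0")
  p <- contour@points
  h <- contour@spacingUm
  .assert(h > 0, "degenerate contour spacing")
  x <- .circSmooth(p[, 1], smoothSigmaUm, h)
  y <- .circSmooth(p[, 2], smoothSigmaUm, h)
  # smoothing contracts high-curvature segments, so re-resample to uniform
  # arc length: the central-difference formulae below assume |dp/ds| = 1,
  # and the turning-number identity sum(kappa * h) = 2*pi needs a true
  # arc-length parameterisation
  n <- length(x)
  xc <- c(x, x[1]); yc <- c(y, y[1])
  s <- c(0, cumsum(sqrt(diff(xc)^2 + diff(yc)^2)))
  L <- s[n + 1]
  .assert(L > 0, "degenerate (zero-length) contour")
  sOut <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  x <- approx(s, xc, xout = sOut)$y
  y <- approx(s, yc, xout = sOut)$y
  h <- L / n
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  xp <- (x[ip] - x[im]) / (2 * h); yp <- (y[ip] - y[im]) / (2 * h)
  xpp <- (x[ip] - 2 * x + x[im]) / h^2; ypp <- (y[ip] - 2 * y + y[im]) / h^2
  sp2 <- xp^2 + yp^2
  .assert(all(sp2 > 1e-12), "degenerate (zero-length) contour segment")
  kappa <- (xp * ypp - yp * xpp) / sp2^1.5
  new("CurvatureProfile", arcPositions = (seq_len(n) - 1) * h, kappa = kappa,
      smoothSigmaUm = smoothSigmaUm, perimeterUm = n * h,
      areaUm2 = .shoelace(cbind(x, y)))
}

#' Call boundary invaginations from a curvature profile
#'
#' Maximal circular runs with \eqn{\kappa < -\kappa_{min}} are found (runs
#' wrapping the start/end seam are merged) and kept when their arc length
#' is at least \code{lenMinFrac} of the perimeter. The default curvature
#' threshold scales with nuclear size: \eqn{\kappa_{min} = 0.25 / R_{eq}}
#' with \eqn{R_{eq} = \sqrt{A/\pi}} the equivalent-area radius, which makes
#' the call invariant under physical rescaling.
#'
#' @param profile a \linkS4class{CurvatureProfile}.
#' @param kappaMin curvature threshold (1/um); \code{NULL} for the
#'   size-scaled default.
#' @param kappaMinFactor factor in the default threshold (default 0.25).
#' @param lenMinFrac minimum run length as a fraction of the perimeter
#'   (default 0.02).
#' @return an \linkS4class{InvaginationCall}.
#' @export
detectInvaginations <- function(profile, kappaMin = NULL,
                                kappaMinFactor = 0.25, lenMinFrac = 0.02) {
  .assert(is(profile, "CurvatureProfile"), "profile must be a CurvatureProfile")
  if (is.null(kappaMin)) {
    req <- sqrt(max(profile@areaUm2, 1e-12) / pi)
    kappaMin <- kappaMinFactor / req
  }
  .assert(kappaMin > 0 && lenMinFrac > 0, "thresholds must be > 0")
  k <- profile@kappa
  n <- length(k)
  h <- profile@perimeterUm / n
  lenMinUm <- lenMinFrac * profile@perimeterUm
  neg <- k < -kappaMin
  runs <- data.frame(startUm = numeric(0), endUm = numeric(0),
                     minKappa = numeric(0), lengthUm = numeric(0))
  if (any(neg)) {
    if (all(neg)) {
      runs <- data.frame(startUm = 0, endUm = profile@perimeterUm,
                         minKappa = min(k), lengthUm = profile@perimeterUm)
    } else {
      # rotate so position 1 is outside a run, then find contiguous blocks
      off <- which(!neg)[1]
      negR <- neg[c(off:n, seq_len(off - 1L))]
      r <- rle(negR)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (i in which(r$values)) {
        idx <- ((starts[i]:ends[i]) + off - 2L) %% n + 1L
        runs <- rbind(runs, data.frame(
          startUm = profile@arcPositions[idx[1]],
          endUm = profile@arcPositions[idx[length(idx)]],
          minKappa = min(k[idx]),
          lengthUm = length(idx) * h))
      }
    }
    runs <- runs[runs$lengthUm >= lenMinUm, , drop = FALSE]
    runs <- runs[order(runs$startUm), , drop = FALSE]
    rownames(runs) <- NULL
  }
  new("InvaginationCall", runs = runs, invaginated = nrow(runs) > 0L,
      kappaMin = kappaMin, lenMinUm = lenMinUm)
}

#' Score surface wrinkles by Hessian ridge detection
#'
#' The shell (lamin-like) channel is smoothed at the ridge scale, the
#' Hessian is formed by finite differences, and its larger eigenvalue --
#' positive over dark valley lines -- is the ridge response (converted to
#' physical units, intensity/um^2). Hysteresis thresholding keeps weak
#' ridge pixels connected to strong ones, the result is thinned to a 1-px
#' centerline, and the ridge-length density is the centerline length per
#' unit (eroded) nuclear area.
#'
#' @param channel numeric \code{(y, x)} matrix (shell/lamin channel; use
#'   the DAPI channel when no shell stain exists).
#' @param mask a \linkS4class{NucleusMask} or logical matrix.
#' @param pixelSizeUm um per pixel (from the NucleusMask if given).
#' @param scaleUm ridge scale (Gaussian sigma, um; default 0.25).
#' @param marginUm boundary erosion margin in micrometres (default 1.0) so
#'   the nuclear-envelope rim -- itself a strong curvature feature at the
#'   detection scale -- is not scored as a ridge.
#' @param highThreshold,lowThreshold hysteresis thresholds on the ridge
#'   response (intensity/um^2).
#' @param densityMin density (um/um^2) above which the nucleus is called
#'   wrinkled; the default was calibrated on ridge-free vs ridged phantoms.
#' @return a \linkS4class{WrinkleResult}.
#' @export
wrinkleScore <- function(channel, mask, pixelSizeUm = 1, scaleUm = 0.25,
                         marginUm = 1.0, highThreshold = 1.0,
                         lowThreshold = 0.4, densityMin = 0.02) {
  if (is(mask, "NucleusMask")) {
    pixelSizeUm <- mask@pixelSizeUm
    mask <- mask@mask
  }
  em <- .erodeMask(mask, round(marginUm / pixelSizeUm))
  .assert(any(em), "eroded mask is empty; decrease marginUm")
  sm <- .gaussBlur(channel, scaleUm / pixelSizeUm)
  Ixx <- .shiftMat(sm, 0, -1) - 2 * sm + .shiftMat(sm, 0, 1)
  Iyy <- .shiftMat(sm, -1, 0) - 2 * sm + .shiftMat(sm, 1, 0)
  Ixy <- (.shiftMat(sm, -1, -1) + .shiftMat(sm, 1, 1) -
            .shiftMat(sm, -1, 1) - .shiftMat(sm, 1, -1)) / 4
  disc <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  eigMax <- (Ixx + Iyy) / 2 + disc
  resp <- pmax(eigMax, 0) / pixelSizeUm^2    # intensity per um^2
  resp[!em] <- 0
  strong <- resp >= highThreshold
  weak <- resp >= lowThreshold
  if (any(strong)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(weak * 1)))
    keep <- unique(lab[strong])
    ridge <- matrix(lab %in% keep & lab > 0, nrow(lab), ncol(lab))
  } else ridge <- matrix(FALSE, nrow(resp), ncol(resp))
  sk <- if (any(ridge)) .thinZS(ridge) else ridge
  lenUm <- .skeletonLengthPx(sk) * pixelSizeUm
  areaUm2 <- sum(em) * pixelSizeUm^2
  dens <- lenUm / areaUm2
  new("WrinkleResult", ridgeLengthDensity = dens,
      wrinkled = dens > densityMin, skeleton = sk, densityMin = densityMin)
}

#' 3D nuclear geometry from a voxel mask
#'
#' Volume is the voxel count times the voxel volume; area is the largest
#' single-plane cross-section; height is the occupied z-extent
#' \code{(zmax - zmin + 1) * zStep}.
#'
#' @param mask3d logical array \code{(y, x, z)}.
#' @param pixelSizeUm in-plane voxel size (um).
#' @param zStepUm plane spacing (um).
#' @return named numeric: \code{areaUm2}, \code{volumeUm3}, \code{heightUm}.
#' @export
nucleusGeometry <- function(mask3d, pixelSizeUm, zStepUm) {
  .assert(length(dim(mask3d)) == 3L, "mask3d must be a (y, x, z) array")
  .assert(any(mask3d), "empty mask")
  .assert(pixelSizeUm > 0 && zStepUm > 0, "voxel sizes must be > 0")
  perPlane <- apply(mask3d, 3, sum)
  zOcc <- which(perPlane > 0)
  c(areaUm2 = max(perPlane) * pixelSizeUm^2,
    volumeUm3 = sum(perPlane) * pixelSizeUm^2 * zStepUm,
    heightUm = (max(zOcc) - min(zOcc) + 1) * zStepUm)
}

#' 2D shape descriptors from second central moments
#'
#' Area from the pixel count; aspect ratio and orientation from the
#' equivalent ellipse of the second central moments. Orientation is the
#' major-axis angle in degrees, in \code{(-90, 90]}, measured from the
#' image x axis.
#'
#' @param mask a \linkS4class{NucleusMask} or logical matrix.
#' @param pixelSizeUm um per pixel (from the NucleusMask if given).
#' @return named numeric: \code{areaUm2}, \code{aspectRatio},
#'   \code{orientationDeg}.
#' @export
shapeDescriptors <- function(mask, pixelSizeUm = 1) {
  if (is(mask, "NucleusMask")) {
    pixelSizeUm <- mask@pixelSizeUm
    mask <- mask@mask
  }
  .assert(any(mask), "empty mask")
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  mx <- mean(x); my <- mean(y)
  mxx <- mean((x - mx)^2) + 1 / 12    # + pixel variance
  myy <- mean((y - my)^2) + 1 / 12
  mxy <- mean((x - mx) * (y - my))
  tr <- mxx + myy; dt <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr / 2 + dt; l2 <- tr / 2 - dt
  ang <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  c(areaUm2 = length(y) * pixelSizeUm^2,
    aspectRatio = sqrt(l1 / max(l2, 1e-12)),
    orientationDeg = ang)
}

#' Mean in-mask intensity
#'
#' @param channel numeric \code{(y, x)} matrix.
#' @param mask logical matrix (or \linkS4class{NucleusMask}).
#' @param backgroundSubtract subtract the mode of the out-of-mask pixels
#'   (histogram mode, 256 bins) before averaging.
#' @return scalar mean intensity.
#' @export
meanIntensity <- function(channel, mask, backgroundSubtract = FALSE) {
  if (is(mask, "NucleusMask")) mask <- mask@mask
  .assert(any(mask), "empty mask")
  v <- mean(channel[mask])
  if (backgroundSubtract) {
    bg <- channel[!mask]
    if (length(bg)) {
      if (diff(range(bg)) == 0) mode_ <- bg[1]
      else {
        h <- graphics::hist(bg, breaks = 256, plot = FALSE)
        mode_ <- h$mids[which.max(h$counts)]
      }
      v <- v - mode_
    }
  }
  v
}

#' Nucleocytoplasmic intensity ratio
#'
#' Mean intensity inside the nucleus divided by the mean over the
#' cytoplasm (cell minus nucleus). Values above 1 indicate nuclear
#' enrichment of the marker.
#'
#' @param channel numeric \code{(y, x)} matrix.
#' @param nucleusMask,cellMask logical matrices with
#'   \code{nucleusMask} contained in \code{cellMask}.
#' @return scalar ratio.
#' @export
nucleocytoplasmicRatio <- function(channel, nucleusMask, cellMask) {
  if (is(nucleusMask, "NucleusMask")) nucleusMask <- nucleusMask@mask
  .assert(all(cellMask[nucleusMask]), "nucleusMask must lie within cellMask")
  cyto <- cellMask & !nucleusMask
  .assert(any(cyto), "cytoplasm region is empty")
  mean(channel[nucleusMask]) / mean(channel[cyto])
}

#' Fraction of values strictly above a threshold
#'
#' The positive-cell fraction readout (e.g. Ki67- or ALP-positive cells).
#'
#' @param values numeric vector of per-cell readouts.
#' @param threshold positivity cutoff.
#' @return fraction in [0, 1].
#' @export
positiveFraction <- function(values, threshold) {
  .assert(length(values) > 0, "empty value list")
  mean(values > threshold)
}
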