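# Nucleus segmentation and subpixel contour extraction.

#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing, Otsu threshold, hole filling, connected-component
#' labelling; components touching the image border (optional) and below the
#' minimum area are removed. For z-stacks pass the maximum-intensity
#' projection (\code{getChannel(img, "DAPI", z = "max")}).
#'
#' @param channel numeric \code{(y, x)} matrix, or an
#'   \linkS4class{ImageStack} (its first channel is used).
#' @param pixelSizeUm um per pixel (taken from the stack if one is given).
#' @param smoothSigmaPx Gaussian sigma in pixels (default 1).
#' @param minAreaPx minimum component area in pixels (default 200).
#' @param excludeBorder drop components touching the image border.
#' @return list of \linkS4class{NucleusMask}; empty (with a warning) for a
#'   blank image.
#' @export
segmentNuclei <- function(channel, pixelSizeUm = 1, smoothSigmaPx = 1,
                          minAreaPx = 200, excludeBorder = TRUE) {
  if (is(channel, "ImageStack")) {
    pixelSizeUm <- pixelSize(channel)
    channel <- getChannel(channel, 1L, if (isStack3D(channel)) "max" else 1L)
  }
  .assert(is.matrix(channel), "channel must be a 2D matrix")
  rng <- range(channel)
  if (rng[2] <= rng[1]) {
    warning("blank image: no foreground found")
    return(list())
  }
  sm <- .gaussBlur(channel, smoothSigmaPx)
  smn <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  bw <- smn > thr
  if (!any(bw)) {
    warning("blank image: no foreground found")
    return(list())
  }
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) >= 0.5
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(filled * 1)))
  out <- list()
  for (l in seq_len(max(lab))) {
    m <- lab == l
    if (sum(m) < minAreaPx) next
    if (excludeBorder &&
        (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)])))
      next
    out[[length(out) + 1L]] <- new("NucleusMask", label = length(out) + 1L,
                                   mask = m, pixelSizeUm = pixelSizeUm,
                                   planeOfFocus = 1L)
  }
  out
}

#' Extract a subpixel boundary contour from a nucleus mask
#'
#' The binary mask is Gaussian-smoothed and the 0.5 iso-contour is traced
#' (marching squares via \code{contourLines}), giving subpixel vertex
#' positions; the polyline is then resampled to uniform arc-length spacing
#' and oriented counterclockwise.
#'
#' @param mask a \linkS4class{NucleusMask}, or a logical matrix.
#' @param pixelSizeUm um per pixel (taken from the NucleusMask if given).
#' @param smoothSigmaPx Gaussian sigma applied to the mask (pixels).
#' @param spacingFactor resampling spacing as a fraction of the pixel size.
#' @return a \linkS4class{Contour} in micrometres.
#' @export
extractContour <- function(mask, pixelSizeUm = 1, smoothSigmaPx = 1,
                           spacingFactor = 0.5) {
  if (is(mask, "NucleusMask")) {
    pixelSizeUm <- mask@pixelSizeUm
    mask <- mask@mask
  }
  .assert(is.matrix(mask), "mask must be a matrix")
  m <- mask * 1
  .assert(!(any(mask[1, ]) || any(mask[nrow(m), ]) || any(mask[, 1]) ||
              any(mask[, ncol(m)])),
          "mask touches the image border; exclude border-touching nuclei")
  sm <- .gaussBlur(m, smoothSigmaPx)
  # contourLines: z[i, j] sits at (x = xgrid[i], y = ygrid[j]); our matrix is
  # [y, x], so the returned $x are image-y and $y are image-x coordinates.
  cl <- contourLines(x = seq_len(nrow(m)) - 1, y = seq_len(ncol(m)) - 1,
                     z = sm, levels = 0.5)
  .assert(length(cl) > 0, "no 0.5-level contour found")
  lens <- vapply(cl, function(s) length(s$x), 1L)
  seg <- cl[[which.max(lens)]]
  pts <- cbind(x = seg$y, y = seg$x)           # back to image (x, y), px
  if (all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  # uniform arc-length resampling (closed)
  ptsC <- rbind(pts, pts[1, ])
  segL <- sqrt(rowSums(diff(ptsC)^2))
  .assert(all(segL >= 0) && sum(segL) > 0, "degenerate contour")
  keep <- c(TRUE, segL > 1e-12)
  ptsC <- ptsC[keep, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums(diff(ptsC)^2))))
  total <- s[length(s)]
  spacing <- spacingFactor                    # in px here
  nOut <- max(16L, round(total / spacing))
  sOut <- seq(0, total, length.out = nOut + 1L)[-(nOut + 1L)]
  xr <- approx(s, ptsC[, 1], xout = sOut)$y
  yr <- approx(s, ptsC[, 2], xout = sOut)$y
  Contour(cbind(xr, yr) * pixelSizeUm,
          spacingUm = total / nOut * pixelSizeUm)
}
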