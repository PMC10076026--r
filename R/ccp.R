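# Chromatin condensation parameter: Sobel edge density within the nucleus.

#' Sobel gradient magnitude within a mask
#'
#' Classic 3x3 Sobel kernels (x kernel rows \code{(-1 0 1; -2 0 2; -1 0 1)}),
#' unnormalised, so a vertical intensity step of height h yields a peak
#' response of 4h. The convolution is computed on the in-mask region with
#' replicate padding at the mask boundary: pixels outside the mask are
#' filled with the value of their nearest in-mask neighbourhood (two
#' dilation passes, enough for the 3x3 support) before convolving, so the
#' nuclear rim itself does not register as an edge. Outside the mask the
#' result is zero.
#'
#' @param channel numeric \code{(y, x)} matrix (DAPI).
#' @param mask logical matrix (or \linkS4class{NucleusMask}).
#' @return gradient magnitude matrix, zero outside the mask.
#' @export
sobelGradient <- function(channel, mask) {
  if (is(mask, "NucleusMask")) mask <- mask@mask
  .assert(is.matrix(channel) && any(mask), "need a 2D channel and a non-empty mask")
  f <- .maskReplicateFill(channel, mask, passes = 2L)
  gx <- .conv3(f, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3))
  gy <- .conv3(f, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3))
  g <- sqrt(gx^2 + gy^2)
  g[!mask] <- 0
  g
}

# fill out-of-mask pixels from the mean of their defined 8-neighbours,
# iterated; leaves distant background at 0 (masked away downstream)
.maskReplicateFill <- function(channel, mask, passes = 2L) {
  f <- channel; f[!mask] <- 0
  def <- mask
  for (p in seq_len(passes)) {
    acc <- matrix(0, nrow(f), ncol(f)); cnt <- matrix(0, nrow(f), ncol(f))
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      acc <- acc + .shiftMat(f * def, dy, dx)
      cnt <- cnt + .shiftMat(def * 1, dy, dx)
    }
    newPix <- !def & cnt > 0
    f[newPix] <- acc[newPix] / cnt[newPix]
    def <- def | newPix
  }
  f
}

# 3x3 correlation with replicate edges (kernel given in [ky, kx] layout)
.conv3 <- function(m, k) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1)
    out <- out + k[dy + 2, dx + 2] * .shiftMat(m, -dy, -dx)
  out
}

#' Compute the chromatin condensation parameter (CCP)
#'
#' Edge pixels are the in-mask pixels whose Sobel gradient magnitude
#' exceeds a threshold; CCP is their count divided by the nuclear area in
#' pixels -- the density of visible chromatin edges normalised to the
#' cross-sectional area. Threshold rules: \code{"otsu"} (default; Otsu on
#' the in-mask gradient histogram), \code{"fraction"} (a fixed fraction of
#' the in-mask gradient maximum), or \code{"fixed"} (an absolute cutoff
#' given in \code{fixedValue}, for comparing images at one common scale,
#' e.g. before/after smoothing). The relative rules make CCP invariant
#' under affine intensity rescaling \code{a*I + b} (a > 0). The applied
#' cutoff is recorded in the result.
#'
#' @param channel numeric \code{(y, x)} matrix (DAPI).
#' @param mask logical matrix (or \linkS4class{NucleusMask}).
#' @param thresholdRule \code{"otsu"}, \code{"fraction"} or \code{"fixed"}.
#' @param fixedFraction fraction of the gradient maximum for the
#'   \code{"fraction"} rule (default 0.25).
#' @param fixedValue absolute gradient cutoff for the \code{"fixed"} rule.
#' @return a \linkS4class{CCPResult}.
#' @export
computeCCP <- function(channel, mask,
                       thresholdRule = c("otsu", "fraction", "fixed"),
                       fixedFraction = 0.25, fixedValue = NULL) {
  if (is(mask, "NucleusMask")) mask <- mask@mask
  thresholdRule <- match.arg(thresholdRule)
  if (thresholdRule == "fixed")
    .assert(is.numeric(fixedValue) && fixedValue >= 0,
            "the 'fixed' rule needs a non-negative fixedValue")
  g <- sobelGradient(channel, mask)
  gm <- g[mask]
  if (max(gm) <= 0 && thresholdRule != "fixed") {
    thr <- 0
    edge <- mask & FALSE
  } else {
    thr <- switch(thresholdRule, otsu = .otsuVec(gm),
                  fraction = fixedFraction * max(gm), fixed = fixedValue)
    edge <- mask & g > thr
  }
  areaPx <- sum(mask)
  new("CCPResult", ccp = sum(edge) / areaPx, edgePixelCount = sum(edge),
      areaPx = as.integer(areaPx), edgeMap = edge, thresholdUsed = thr,
      thresholdRule = thresholdRule)
}
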