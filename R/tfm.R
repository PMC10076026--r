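# Traction force microscopy: drift alignment, PIV displacement, and
# regularised Fourier-transform traction cytometry (FTTC) on the elastic
# half-space.

#' Estimate and correct global drift between two bead images
#'
#' Phase correlation (normalised cross-power spectrum) gives the integer
#' shift; a 3-point Gaussian fit on the correlation peak refines it to
#' subpixel precision. If the correlation peak is below the quality floor
#' a warning is issued and zero shift returned.
#'
#' @param reference,moved numeric matrices of identical shape.
#' @param qualityFloor minimum peak value of the phase-correlation surface
#'   (whose energy is 1) accepted as a genuine shift.
#' @return list with \code{shift} = c(dx, dy) in pixels (the displacement
#'   of \code{moved} relative to \code{reference}) and \code{aligned} =
#'   \code{moved} resampled onto the reference frame (bilinear).
#' @export
alignDrift <- function(reference, moved, qualityFloor = 0.01) {
  .assert(all(dim(reference) == dim(moved)), "images must have the same shape")
  n1 <- nrow(reference); n2 <- ncol(reference)
  Fr <- fft(reference - mean(reference))
  Fm <- fft(moved - mean(moved))
  R <- Fr * Conj(Fm)
  corrRaw <- Re(fft(R, inverse = TRUE)) / (n1 * n2)
  Rn <- R / pmax(Mod(R), 1e-12)
  corr <- Re(fft(Rn, inverse = TRUE)) / (n1 * n2)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  if (max(corr) < qualityFloor) {
    warning("phase-correlation peak below quality floor; assuming zero drift")
    return(list(shift = c(dx = 0, dy = 0), aligned = moved))
  }
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  idx <- function(i, n) (i - 1) %% n + 1
  iy <- pk[1]; ix <- pk[2]
  # the correlation peak sits at -s where moved(x) = reference(x - s);
  # subpixel refinement uses the raw (smooth) cross-correlation surface,
  # the phase-correlation peak only locates the integer part robustly
  py <- wrap(iy, n1) + .gauss3(corrRaw[idx(iy - 1, n1), ix],
                               corrRaw[iy, ix],
                               corrRaw[idx(iy + 1, n1), ix])
  px_ <- wrap(ix, n2) + .gauss3(corrRaw[iy, idx(ix - 1, n2)],
                                corrRaw[iy, ix],
                                corrRaw[iy, idx(ix + 1, n2)])
  sy <- -py; sx <- -px_
  yy <- matrix(seq_len(n1), n1, n2); xx <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
  aligned <- matrix(.bilinear(moved, yy - sy, xx - sx), n1, n2)
  list(shift = c(dx = sx, dy = sy), aligned = aligned)
}

#' PIV displacement field by windowed cross-correlation
#'
#' The image pair is divided into square interrogation windows; each
#' window pair is zero-mean normalised and cross-correlated via FFT, the
#' correlation peak located, and refined to subpixel precision with a
#' 3-point Gaussian fit per axis. Vector quality is the ratio of the
#' primary peak to the secondary peak (outside a 3x3 exclusion zone);
#' low-quality vectors are replaced by the median of their neighbours and
#' flagged in \code{replaced}.
#'
#' @param reference,displaced numeric matrices of identical shape.
#' @param windowPx interrogation window side (>= 16).
#' @param overlapFrac window overlap fraction in [0, 1).
#' @param pixelSizeUm um per pixel (grid coordinates and displacements are
#'   returned in um).
#' @param minQuality peak-ratio floor below which a vector is replaced.
#' @return a \linkS4class{DisplacementField}.
#' @export
pivDisplacement <- function(reference, displaced, windowPx = 32L,
                            overlapFrac = 0.5, pixelSizeUm = 1,
                            minQuality = 1.3) {
  .assert(all(dim(reference) == dim(displaced)), "images must share a shape")
  .assert(windowPx >= 16L, "window must be >= 16 px")
  .assert(overlapFrac >= 0 && overlapFrac < 1, "overlap must be in [0, 1)")
  .assert(windowPx <= min(dim(reference)), "window larger than image")
  w <- as.integer(windowPx)
  step <- max(1L, as.integer(round(w * (1 - overlapFrac))))
  ys <- seq(1L, nrow(reference) - w + 1L, by = step)
  xs <- seq(1L, ncol(reference) - w + 1L, by = step)
  ny <- length(ys); nx <- length(xs)
  ux <- uy <- qual <- matrix(NA_real_, ny, nx)
  wrap <- function(i) if (i - 1 > w / 2) i - 1 - w else i - 1
  idx <- function(i) (i - 1) %% w + 1
  xcorr <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
    if (sa < 1e-12 || sb < 1e-12) return(NULL)
    F <- Conj(fft(a)) * fft(b)
    list(cc = Re(fft(F, inverse = TRUE)) / (w * w) / (sa * sb), F = F)
  }
  freqs <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1)
  # evaluate the correlation surface at fractional lags around a peak by
  # direct (matrix) DFT and return the refined subpixel argmax; avoids the
  # peak-locking bias of 3-point fits near half-pixel displacements
  upsampledPeak <- function(F, cy, cx, half = 1, step = 0.02) {
    ty <- cy + seq(-half, half, by = step)
    tx <- cx + seq(-half, half, by = step)
    Ey <- exp(2i * pi * outer(ty, freqs) / w)
    Ex <- exp(2i * pi * outer(freqs, tx) / w)
    S <- Re(Ey %*% F %*% Ex)
    p <- which(S == max(S), arr.ind = TRUE)[1, ]
    # parabolic polish on the fine grid (interior points only)
    py <- ty[p[1]]; px <- tx[p[2]]
    if (p[1] > 1 && p[1] < length(ty)) {
      d <- (S[p[1] - 1, p[2]] - S[p[1] + 1, p[2]]) /
        (2 * (S[p[1] - 1, p[2]] + S[p[1] + 1, p[2]] - 2 * S[p[1], p[2]]))
      if (is.finite(d) && abs(d) <= 1) py <- py + d * step
    }
    if (p[2] > 1 && p[2] < length(tx)) {
      d <- (S[p[1], p[2] - 1] - S[p[1], p[2] + 1]) /
        (2 * (S[p[1], p[2] - 1] + S[p[1], p[2] + 1] - 2 * S[p[1], p[2]]))
      if (is.finite(d) && abs(d) <= 1) px <- px + d * step
    }
    c(py, px)
  }
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    a <- reference[ys[iy]:(ys[iy] + w - 1L), xs[ix]:(xs[ix] + w - 1L)]
    b <- displaced[ys[iy]:(ys[iy] + w - 1L), xs[ix]:(xs[ix] + w - 1L)]
    z <- xcorr(a, b)
    if (is.null(z)) { ux[iy, ix] <- 0; uy[iy, ix] <- 0; qual[iy, ix] <- 0; next }
    cc <- z$cc
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    # window-offset passes: re-read the displaced window at the integer
    # peak and iterate until the residual integer peak is zero, so the
    # refined correlation peak is symmetric -- this removes the
    # in-plane-loss bias of the 3-point fit and makes integer
    # displacements recover exactly
    oy <- 0L; ox <- 0L
    for (pass in 1:3) {
      oy2 <- min(max(ys[iy] + oy + wrap(pk[1]), 1L),
                 nrow(reference) - w + 1L) - ys[iy]
      ox2 <- min(max(xs[ix] + ox + wrap(pk[2]), 1L),
                 ncol(reference) - w + 1L) - xs[ix]
      if (pass > 1 && oy2 == oy && ox2 == ox) break
      oy <- oy2; ox <- ox2
      b2 <- displaced[(ys[iy] + oy):(ys[iy] + oy + w - 1L),
                      (xs[ix] + ox):(xs[ix] + ox + w - 1L)]
      zN <- xcorr(a, b2)
      if (is.null(zN)) break
      z <- zN; cc <- z$cc
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (wrap(pk[1]) == 0L && wrap(pk[2]) == 0L) break
    }
    sub <- upsampledPeak(z$F, wrap(pk[1]), wrap(pk[2]))
    dy <- oy + sub[1]
    dx <- ox + sub[2]
    # peak ratio quality: exclude 3x3 around the peak
    cc2 <- cc
    for (qy in -1:1) for (qx in -1:1)
      cc2[idx(pk[1] + qy), idx(pk[2] + qx)] <- -Inf
    second <- max(cc2)
    qual[iy, ix] <- if (second > 0) max(cc) / second else Inf
    ux[iy, ix] <- dx; uy[iy, ix] <- dy
  }
  replaced <- qual < minQuality
  if (any(replaced)) {
    for (i in which(replaced)) {
      iy <- (i - 1) %% ny + 1; ix <- (i - 1) %/% ny + 1
      ny0 <- max(1, iy - 1):min(ny, iy + 1)
      nx0 <- max(1, ix - 1):min(nx, ix + 1)
      nb <- !replaced[ny0, nx0]
      if (any(nb)) {
        ux[iy, ix] <- median(ux[ny0, nx0][nb])
        uy[iy, ix] <- median(uy[ny0, nx0][nb])
      }
    }
  }
  new("DisplacementField",
      x = (xs - 1 + (w - 1) / 2) * pixelSizeUm,
      y = (ys - 1 + (w - 1) / 2) * pixelSizeUm,
      ux = ux * pixelSizeUm, uy = uy * pixelSizeUm,
      quality = qual, replaced = replaced)
}

#' Fourier-transform traction cytometry (FTTC)
#'
#' Inverts the Boussinesq half-space relation between surface traction and
#' surface displacement per wavevector, with zeroth-order Tikhonov
#' regularisation: \eqn{T = (G^T G + \lambda^2 I)^{-1} G^T u}. The
#' zero-frequency component is set to zero, enforcing zero net force. With
#' \eqn{\lambda = 0} this is the exact inverse of the forward model on the
#' same grid.
#'
#' @param disp a \linkS4class{DisplacementField} on a uniform grid (um).
#' @param gel a \linkS4class{GelModel}.
#' @param lambda Tikhonov parameter (>= 0), in the units of G (um/Pa);
#'   \code{"gcv"} (recommended for noisy displacement fields) selects it by
#'   generalized cross-validation, computed exactly from the per-wavevector
#'   filter factors; \code{"lcurve"} selects the L-curve corner over a
#'   log-spaced grid of 20 values. The selected value is recorded in the
#'   result.
#' @param window \code{"none"} (default) or \code{"hann"}: optional
#'   tapering of the displacement field to suppress periodic-boundary
#'   leakage for fields that do not decay inside the field of view.
#' @return a \linkS4class{TractionField} on the same grid.
#' @export
fttcTraction <- function(disp, gel, lambda = 0, window = c("none", "hann")) {
  .assert(is(disp, "DisplacementField"), "disp must be a DisplacementField")
  .assert(is(gel, "GelModel"), "gel must be a GelModel")
  window <- match.arg(window)
  if (identical(lambda, "lcurve")) return(.fttcLcurve(disp, gel, window))
  if (identical(lambda, "gcv")) return(.fttcGcv(disp, gel, window))
  .assert(is.numeric(lambda) && lambda >= 0, "lambda must be >= 0")
  ux <- disp@ux; uy <- disp@uy
  if (window == "hann") {
    n1 <- nrow(ux); n2 <- ncol(ux)
    h1 <- 0.5 * (1 - cos(2 * pi * (seq_len(n1) - 1) / (n1 - 1)))
    h2 <- 0.5 * (1 - cos(2 * pi * (seq_len(n2) - 1) / (n2 - 1)))
    H <- outer(h1, h2)
    ux <- ux * H; uy <- uy * H
  }
  spacing <- disp@x[2] - disp@x[1]
  n1 <- nrow(ux); n2 <- ncol(ux)
  kx <- 2 * pi * c(0:(floor(n2 / 2)), -(ceiling(n2 / 2) - 1):-1) / (n2 * spacing)
  ky <- 2 * pi * c(0:(floor(n1 / 2)), -(ceiling(n1 / 2) - 1):-1) / (n1 * spacing)
  KX <- matrix(kx, n1, n2, byrow = TRUE); KY <- matrix(ky, n1, n2)
  K <- sqrt(KX^2 + KY^2); K[1, 1] <- 1
  pref <- 2 * (1 + gel@nu) / (gel@E * K^3)
  Gxx <- pref * ((1 - gel@nu) * K^2 + gel@nu * KY^2)
  Gyy <- pref * ((1 - gel@nu) * K^2 + gel@nu * KX^2)
  Gxy <- -pref * gel@nu * KX * KY
  Ux <- fft(ux); Uy <- fft(uy)
  # G symmetric: T = (G^2 + lambda^2 I)^{-1} G u, closed form per 2x2
  A <- Gxx^2 + Gxy^2 + lambda^2
  Bm <- Gxy * (Gxx + Gyy)
  Cm <- Gyy^2 + Gxy^2 + lambda^2
  det <- A * Cm - Bm^2
  Rx <- Gxx * Ux + Gxy * Uy
  Ry <- Gxy * Ux + Gyy * Uy
  Tx <- (Cm * Rx - Bm * Ry) / det
  Ty <- (-Bm * Rx + A * Ry) / det
  Tx[1, 1] <- 0; Ty[1, 1] <- 0
  tx <- Re(fft(Tx, inverse = TRUE)) / (n1 * n2)
  ty <- Re(fft(Ty, inverse = TRUE)) / (n1 * n2)
  tx <- tx - mean(tx); ty <- ty - mean(ty)
  new("TractionField", x = disp@x, y = disp@y, tx = tx, ty = ty,
      lambda = if (is.numeric(lambda)) lambda else NA_real_)
}

# GCV selection. In the eigenbasis of the (symmetric, per-wavevector 2x2)
# Green operator the Tikhonov filter factors are f_i = g_i^2/(g_i^2+l^2),
# so GCV(l) = sum_i (1-f_i)^2 |u_i|^2 / (sum_i (1-f_i))^2 in closed form.
.fttcGcv <- function(disp, gel, window) {
  spacing <- disp@x[2] - disp@x[1]
  n1 <- nrow(disp@ux); n2 <- ncol(disp@ux)
  kx <- 2 * pi * c(0:(floor(n2 / 2)), -(ceiling(n2 / 2) - 1):-1) / (n2 * spacing)
  ky <- 2 * pi * c(0:(floor(n1 / 2)), -(ceiling(n1 / 2) - 1):-1) / (n1 * spacing)
  KX <- matrix(kx, n1, n2, byrow = TRUE); KY <- matrix(ky, n1, n2)
  K <- sqrt(KX^2 + KY^2); K[1, 1] <- 1
  pref <- 2 * (1 + gel@nu) / (gel@E * K^3)
  Gxx <- pref * ((1 - gel@nu) * K^2 + gel@nu * KY^2)
  Gyy <- pref * ((1 - gel@nu) * K^2 + gel@nu * KX^2)
  Gxy <- -pref * gel@nu * KX * KY
  tr2 <- (Gxx + Gyy) / 2; disc <- sqrt(((Gxx - Gyy) / 2)^2 + Gxy^2)
  g1 <- tr2 + disc; g2 <- tr2 - disc
  Ux <- fft(disp@ux); Uy <- fft(disp@uy)
  # project u onto the eigenvectors (v1 along the discriminant direction)
  a <- Gxy; b <- g1 - Gxx
  nv <- sqrt(a^2 + b^2); nv[nv < 1e-300] <- 1
  e1x <- a / nv; e1y <- b / nv
  noRot <- abs(Gxy) < 1e-300                 # degenerate: already diagonal
  e1x[noRot] <- 1; e1y[noRot] <- 0
  U1 <- e1x * Ux + e1y * Uy
  U2 <- -e1y * Ux + e1x * Uy
  P1 <- Mod(U1)^2; P2 <- Mod(U2)^2
  P1[1, 1] <- 0; P2[1, 1] <- 0               # zero-mode excluded
  lams <- 10^seq(-8, 0, length.out = 40) *
    2 * (1 + gel@nu) / (gel@E * (2 * pi / (n1 * spacing)))
  gcv <- vapply(lams, function(l) {
    w1 <- l^2 / (g1^2 + l^2); w2 <- l^2 / (g2^2 + l^2)
    num <- sum(w1^2 * P1 + w2^2 * P2)
    den <- (sum(w1) + sum(w2))^2
    num / den
  }, numeric(1))
  fttcTraction(disp, gel, lams[which.min(gcv)], window)
}

# L-curve corner selection: maximum curvature of (log residual, log norm)
.fttcLcurve <- function(disp, gel, window) {
  lams <- 10^seq(-6, 0, length.out = 20)
  # scale to the magnitude of G so the grid is problem-independent
  spacing <- disp@x[2] - disp@x[1]
  gscale <- 2 * (1 + gel@nu) / (gel@E * (2 * pi / (length(disp@x) * spacing)))
  lams <- lams * gscale
  res <- nrm <- numeric(length(lams))
  for (i in seq_along(lams)) {
    tf <- fttcTraction(disp, gel, lams[i], window)
    fwd <- .halfspaceForward(tf@tx, tf@ty, gel@E, gel@nu, spacing)
    res[i] <- sqrt(sum((fwd$ux - disp@ux)^2 + (fwd$uy - disp@uy)^2))
    nrm[i] <- sqrt(sum(tf@tx^2 + tf@ty^2))
  }
  lr <- log10(pmax(res, 1e-300)); ln <- log10(pmax(nrm, 1e-300))
  # Menger curvature of consecutive triples along the (log res, log norm)
  # curve; the numerically flat small-lambda tail (residual and norm both
  # unchanged) is excluded so its round-off wiggles cannot win
  curv <- rep(-Inf, length(lams))
  for (i in 2:(length(lams) - 1)) {
    if (abs(lr[i + 1] - lr[i - 1]) < 1e-3 && abs(ln[i + 1] - ln[i - 1]) < 1e-3)
      next
    A <- c(lr[i - 1], ln[i - 1]); B <- c(lr[i], ln[i]); C <- c(lr[i + 1], ln[i + 1])
    cross <- (B[1] - A[1]) * (C[2] - A[2]) - (B[2] - A[2]) * (C[1] - A[1])
    dAB <- sqrt(sum((B - A)^2)); dBC <- sqrt(sum((C - B)^2)); dCA <- sqrt(sum((C - A)^2))
    den <- dAB * dBC * dCA
    if (den > 0) curv[i] <- 2 * cross / den     # signed: convex corner > 0
  }
  best <- lams[which.max(curv)]
  out <- fttcTraction(disp, gel, best, window)
  out
}

#' Mean traction magnitude under a cell mask
#'
#' @param traction a \linkS4class{TractionField}.
#' @param cellMask logical matrix in image pixel space, or \code{NULL} for
#'   the whole grid.
#' @param pixelSizeUm um per pixel of \code{cellMask}'s image.
#' @return mean of |T| (Pa) over grid nodes inside the mask.
#' @export
meanTraction <- function(traction, cellMask = NULL, pixelSizeUm = 1) {
  mag <- sqrt(traction@tx^2 + traction@ty^2)
  if (is.null(cellMask)) return(mean(mag))
  # map grid nodes (um) into mask pixels
  iy <- round(traction@y / pixelSizeUm) + 1L
  ix <- round(traction@x / pixelSizeUm) + 1L
  keep <- outer(iy >= 1 & iy <= nrow(cellMask), ix >= 1 & ix <= ncol(cellMask), "&")
  sel <- matrix(FALSE, length(iy), length(ix))
  for (r in seq_along(iy)) for (c in seq_along(ix)) {
    if (keep[r, c]) sel[r, c] <- cellMask[iy[r], ix[c]]
  }
  .assert(any(sel), "cell mask does not overlap the traction grid")
  mean(mag[sel])
}
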