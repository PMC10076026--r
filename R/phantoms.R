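# Synthetic microscopy phantoms with exact ground truth.
#
# Boundary model: an ellipse radius function r0(theta) = a*b /
# sqrt((b cos)^2 + (a sin)^2), indented by cosine bumps
#   r(theta) = r0(theta) - depth * Req * bump((theta - theta_j) / w)
# with bump(u) = (1 + cos(2*pi*u)) / 2 on |u| <= 1/2. Each sufficiently
# deep, non-overlapping bump produces exactly one contiguous
# negative-curvature arc, which gives analytic control of the invagination
# ground truth. Req = sqrt(a*b) is the equivalent radius.

# radius function and its analytic evaluation on a dense theta grid
.phantomRadius <- function(theta, a, b, lobeTheta, lobeWidth, depthUm) {
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (length(lobeTheta)) {
    for (j in seq_along(lobeTheta)) {
      d <- theta - lobeTheta[j]
      d <- atan2(sin(d), cos(d))            # wrap to (-pi, pi]
      inL <- abs(d) <= lobeWidth[j] / 2
      r[inL] <- r[inL] - depthUm[j] * (1 + cos(2 * pi * d[inL] / lobeWidth[j])) / 2
    }
  }
  r
}

# signed curvature of the polar curve r(theta) on a dense periodic grid,
# by high-resolution central differences of the closed-form radius
.polarCurvature <- function(r, dtheta) {
  n <- length(r)
  rp <- (r[c(2:n, 1)] - r[c(n, 1:(n - 1))]) / (2 * dtheta)
  rpp <- (r[c(2:n, 1)] - 2 * r + r[c(n, 1:(n - 1))]) / dtheta^2
  (r^2 + 2 * rp^2 - r * rpp) / (r^2 + rp^2)^1.5
}

# count maximal circular runs of negative values
.circNegRuns <- function(k) {
  neg <- k < 0
  if (!any(neg)) return(0L)
  if (all(neg)) return(1L)
  starts <- sum(neg & !c(neg[length(neg)], neg[-length(neg)]))
  as.integer(starts)
}

#' Generate a synthetic nucleus image with ground truth
#'
#' Produces a 2-channel (DAPI-like + lamin-like shell) 2D plane, or a
#' single-channel z-stack when \code{spec} has a third semi-axis. The DAPI
#' boundary is the lobed ellipse described in \linkS4class{PhantomSpec};
#' interior texture comes from \code{\link{makeCondensationTexture}}; the
#' shell channel carries the envelope rim plus \code{nWrinkles} dark
#' Gaussian-profile ridge folds crossing the interior. Identical spec and
#' seed give bit-identical pixels.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{image} (\linkS4class{ImageStack}) and
#'   \code{truth}, a list holding: \code{mask} (exact in/out of the true
#'   boundary), \code{contourUm} (dense true boundary polygon, um),
#'   \code{kappaTrue} (analytic curvature on that polygon),
#'   \code{negativeArcCount}, \code{invaginated}, \code{lobeThetas},
#'   \code{lobeWidth}, \code{wrinkled}, \code{wrinkleSegmentsUm},
#'   \code{wrinkleLengthUm}, \code{wrinkleRegion} (eroded mask the length
#'   refers to), \code{condensationLevel}, \code{areaUm2},
#'   \code{ncEnrichment}, and for 3D stacks \code{mask3d},
#'   \code{volumeUm3}, \code{heightUm}, \code{midplaneAreaUm2}.
#' @export
makeNucleusPhantom <- function(spec) {
  .assert(is(spec, "PhantomSpec"), "spec must be a PhantomSpec")
  set.seed(spec@seed)
  px <- spec@pixelSizeUm
  a <- spec@a; b <- spec@b
  req <- sqrt(a * b)

  nL <- spec@nInvaginations
  if (nL > 0L) {
    gap <- 2 * pi / nL
    .assert(spec@invaginationWidth < gap,
            "overlapping lobes: invaginationWidth must be < 2*pi/nInvaginations")
    offset <- runif(1, 0, 2 * pi)
    jitter <- runif(nL, -0.15, 0.15) * (gap - spec@invaginationWidth)
    lobeTheta <- (offset + gap * (seq_len(nL) - 1) + jitter) %% (2 * pi)
    lobeWidth <- rep(spec@invaginationWidth, nL)
    depthUm <- rep(spec@invaginationDepth * req, nL)
  } else {
    lobeTheta <- numeric(0); lobeWidth <- numeric(0); depthUm <- numeric(0)
  }

  # analytic ground-truth boundary and curvature
  nTheta <- 4096L
  theta <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  rT <- .phantomRadius(theta, a, b, lobeTheta, lobeWidth, depthUm)
  .assert(min(rT) > 0.15 * req,
          "lobes pinch the shape: depth too large for this geometry")
  kT <- .polarCurvature(rT, 2 * pi / nTheta)
  negRuns <- .circNegRuns(kT)

  margin <- 2                      # um of background around the shape
  halfX <- a + margin; halfY <- b + margin
  nx <- 2L * ceiling(halfX / px); ny <- 2L * ceiling(halfY / px)
  cx <- (nx - 1) / 2 * px; cy <- (ny - 1) / 2 * px
  xs <- (seq_len(nx) - 1) * px; ys <- (seq_len(ny) - 1) * px
  dx <- matrix(xs, ny, nx, byrow = TRUE) - cx
  dy <- matrix(ys, ny, nx) - cy
  thPix <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  rB <- matrix(.phantomRadius(as.vector(thPix), a, b, lobeTheta, lobeWidth,
                              depthUm), ny, nx)
  mask <- rho <= rB
  # antialiased indicator for subpixel boundary accuracy
  dapi <- pmin(pmax((rB - rho) / px + 0.5, 0), 1) * 0.55

  # chromatin texture (nested foci: deterministic given seed via substream)
  if (spec@condensationLevel > 0) {
    tex <- makeCondensationTexture(spec@condensationLevel, mask,
                                   pixelSizeUm = px,
                                   seed = .substreamSeed(spec@seed, 104729))
    dapi <- dapi + tex
  }

  # shell channel: rim + interior + dark ridge folds (wrinkles)
  sigR <- 0.3
  shell <- 0.25 + 0.55 * exp(-(rho - rB)^2 / (2 * sigR^2))
  shell[!mask & rho > rB + 3 * sigR] <- 0.02
  wrinkleSegs <- list(); wrinkleLen <- 0
  # ground-truth ridge length is reported inside the same 1.0 um eroded
  # region the wrinkle detector scores by default
  erodedMask <- .erodeMask(mask, round(1.0 / px))
  nW <- spec@nWrinkles
  # draw up to 8 fold parameters from a fixed substream, use the first nW:
  # nesting makes ridge length strictly increasing in nW at fixed seed
  set.seed(.substreamSeed(spec@seed, 15485863))
  maxW <- 8L
  phiAll <- (pi * (seq_len(maxW) - 1) / maxW + runif(1, 0, pi) +
               runif(maxW, -0.1, 0.1)) %% pi
  offAll <- runif(maxW, -0.35, 0.35)
  if (nW > 0L) for (k in seq_len(nW)) {
    phi <- phiAll[k]
    # line through point P = center + off * Req * normal, direction (cos, sin)
    nxv <- -sin(phi); nyv <- cos(phi)
    px0 <- cx + offAll[k] * req * nxv; py0 <- cy + offAll[k] * req * nyv
    # perpendicular distance of every pixel to the line
    dist <- abs((dx + cx - px0) * nxv + (dy + cy - py0) * nyv)
    sigW <- 0.25
    valley <- 0.4 * exp(-dist^2 / (2 * sigW^2))
    shell[mask] <- shell[mask] - valley[mask]
    # ground-truth centerline length inside the eroded region
    tline <- seq(-(a + b), a + b, by = px / 4)
    lx <- px0 + tline * cos(phi); ly <- py0 + tline * sin(phi)
    ii <- round(ly / px) + 1; jj <- round(lx / px) + 1
    ok <- ii >= 1 & ii <= ny & jj >= 1 & jj <= nx
    inReg <- rep(FALSE, length(tline))
    inReg[ok] <- erodedMask[cbind(ii[ok], jj[ok])]
    segLen <- sum(inReg) * px / 4
    wrinkleLen <- wrinkleLen + segLen
    if (segLen > 0) {
      tIn <- tline[inReg]
      wrinkleSegs[[length(wrinkleSegs) + 1L]] <-
        rbind(c(px0 + min(tIn) * cos(phi), py0 + min(tIn) * sin(phi)),
              c(px0 + max(tIn) * cos(phi), py0 + max(tIn) * sin(phi)))
    }
  }
  shell <- pmin(pmax(shell, 0), 1)

  # marker channel with nuclear enrichment for nucleocytoplasmic readouts
  cellMask <- rho <= 1.6 * rB
  marker <- matrix(0.02, ny, nx)
  marker[cellMask] <- 0.3
  marker[mask] <- 0.3 * spec@ncEnrichment

  # noise (applied identically per channel, independent draws)
  set.seed(.substreamSeed(spec@seed, 32452843))
  addNoise <- function(m) {
    if (spec@noisePoissonGain > 0)
      m <- rpois(length(m), pmax(m, 0) * spec@noisePoissonGain) /
        spec@noisePoissonGain
    if (spec@noiseGaussianSd > 0)
      m <- m + rnorm(length(m), 0, spec@noiseGaussianSd)
    matrix(pmax(m, 0), ny, nx)
  }
  dapi <- addNoise(pmin(dapi, 1)); shell <- addNoise(shell)
  marker <- addNoise(marker)

  truth <- list(
    mask = mask,
    contourUm = cbind(x = cx + rT * cos(theta), y = cy + rT * sin(theta)),
    kappaTrue = kT, negativeArcCount = negRuns,
    invaginated = negRuns > 0L,
    lobeThetas = lobeTheta, lobeWidth = spec@invaginationWidth,
    wrinkled = nW > 0L, wrinkleSegmentsUm = wrinkleSegs,
    wrinkleLengthUm = wrinkleLen, wrinkleRegion = erodedMask,
    condensationLevel = spec@condensationLevel,
    areaUm2 = .shoelace(cbind(rT * cos(theta), rT * sin(theta))),
    ncEnrichment = spec@ncEnrichment,
    cellMask = cellMask
  )

  if (!is.na(spec@c)) {
    cc <- spec@c; zs <- spec@zStepUm
    zCent <- cc + zs / 2                     # nucleus spans z in [0, 2c]
    nz <- ceiling(2 * cc / zs)
    zPos <- (seq_len(nz) - 0.5) * zs
    pix <- array(0, dim = c(ny, nx, 1L, nz))
    mask3d <- array(FALSE, dim = c(ny, nx, nz))
    for (iz in seq_len(nz)) {
      s2 <- 1 - ((zPos[iz] - zCent) / cc)^2
      if (s2 <= 0) next
      s <- sqrt(s2)
      rZ <- matrix(.phantomRadius(as.vector(thPix), a * s, b * s,
                                  lobeTheta, lobeWidth, depthUm * s), ny, nx)
      mask3d[, , iz] <- rho <= rZ
      pix[, , 1L, iz] <- pmin(pmax((rZ - rho) / px + 0.5, 0), 1) * 0.55
    }
    truth$mask3d <- mask3d
    truth$volumeUm3 <- 4 / 3 * pi * a * b * cc
    truth$heightUm <- 2 * cc
    truth$midplaneAreaUm2 <- pi * a * b
    img <- new("ImageStack", pixels = pix, channelNames = "DAPI",
               pixelSizeUm = px, zStepUm = zs)
  } else {
    pix <- array(0, dim = c(ny, nx, 3L, 1L))
    pix[, , 1L, 1L] <- dapi; pix[, , 2L, 1L] <- shell
    pix[, , 3L, 1L] <- marker
    img <- new("ImageStack", pixels = pix,
               channelNames = c("DAPI", "lamin", "marker"),
               pixelSizeUm = px)
  }
  list(image = img, truth = truth)
}

.erodeMask <- function(mask, marginPx) {
  if (marginPx <= 0L) return(mask)
  kern <- EBImage::makeBrush(2L * marginPx + 1L, shape = "disc")
  em <- EBImage::erode(EBImage::Image(mask * 1), kern)
  EBImage::imageData(em) >= 0.5
}

#' Chromatin condensation texture
#'
#' Renders bright foci and dark "free-space" voids inside a region. The
#' level-to-texture mapping is: \code{nFoci = round(60 * level)} bright
#' Gaussian foci (sd 0.3 um) of amplitude \code{0.35 * (0.4 + 0.6 level)}
#' and \code{nVoids = round(15 * level)} dark voids (sd 0.4 um) of depth
#' \code{0.25 * level}. Foci for lower levels are a prefix of the draw for
#' higher levels at the same seed (nested design), so the internal edge
#' density -- as measured by the package's own Sobel operator -- increases
#' strictly with \code{level}. \code{level = 0} returns a constant 0 patch.
#'
#' @param level condensation level in [0, 1].
#' @param region logical mask; texture is confined to it.
#' @param pixelSizeUm um per pixel.
#' @param seed RNG seed.
#' @return numeric matrix (same shape as \code{region}) of additive
#'   intensity, zero outside the region.
#' @export
makeCondensationTexture <- function(level, region, pixelSizeUm = 0.1,
                                    seed = 1L) {
  .assert(level >= 0 && level <= 1, "level must be in [0, 1]")
  .assert(any(region), "empty region")
  ny <- nrow(region); nx <- ncol(region)
  out <- matrix(0, ny, nx)
  if (level == 0) return(out)
  set.seed(as.integer(seed))
  maxFoci <- 60L; maxVoids <- 15L
  idx <- which(region)
  fociIdx <- sample(idx, maxFoci, replace = TRUE)
  voidIdx <- sample(idx, maxVoids, replace = TRUE)
  nF <- max(1L, round(maxFoci * level)); nV <- round(maxVoids * level)
  amp <- 0.35 * (0.4 + 0.6 * level)
  sigF <- 0.3 / pixelSizeUm; sigV <- 0.4 / pixelSizeUm
  yy <- matrix(seq_len(ny), ny, nx); xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  blob <- function(i, sig, A) {
    cyi <- (i - 1) %% ny + 1; cxi <- (i - 1) %/% ny + 1
    A * exp(-((yy - cyi)^2 + (xx - cxi)^2) / (2 * sig^2))
  }
  for (i in fociIdx[seq_len(nF)]) out <- out + blob(i, sigF, amp)
  if (nV > 0L) for (i in voidIdx[seq_len(nV)])
    out <- out - blob(i, sigV, 0.25 * level)
  out[!region] <- 0
  out
}

#' Generate a per-condition cohort of phantom nuclei
#'
#' Each nucleus is independently invaginated and/or wrinkled with the
#' condition's prevalence; realized labels are recorded in the ground
#' truth. The default imaging noise of the cohort (Gaussian sd 0.02 of the
#' unit dynamic range plus Poisson shot noise at gain 200) is the package's
#' stated benchmark condition for detector performance.
#'
#' @param conditions named list; each element a list with \code{pInvaginated},
#'   \code{pWrinkled}, \code{n} (nuclei per replicate).
#' @param nReplicates technical replicates per condition.
#' @param seed RNG seed.
#' @param depthRange range the per-nucleus invagination depth is drawn from.
#' @param noiseGaussianSd,noisePoissonGain cohort noise model.
#' @param pixelSizeUm sampling.
#' @return list of entries \code{list(image, truth, condition, replicate)}.
#' @export
makeCohort <- function(conditions, nReplicates = 3L, seed = 1L,
                       depthRange = c(0.25, 0.45),
                       noiseGaussianSd = 0.02, noisePoissonGain = 200,
                       pixelSizeUm = 0.1) {
  .assert(length(conditions) >= 1L, "need at least one condition")
  for (cd in conditions) {
    .assert(cd$pInvaginated >= 0 && cd$pInvaginated <= 1 &&
              cd$pWrinkled >= 0 && cd$pWrinkled <= 1,
            "prevalences must be in [0, 1]")
    .assert(cd$n >= 1, "n must be >= 1")
  }
  set.seed(as.integer(seed))
  out <- list()
  for (cond in names(conditions)) {
    cd <- conditions[[cond]]
    for (rep_ in seq_len(nReplicates)) for (i in seq_len(cd$n)) {
      inv <- runif(1) < cd$pInvaginated
      wr <- runif(1) < cd$pWrinkled
      sp <- PhantomSpec(
        a = runif(1, 7, 9), b = runif(1, 5.5, 6.5),
        nInvaginations = if (inv) sample(1:3, 1) else 0L,
        invaginationDepth = runif(1, depthRange[1], depthRange[2]),
        nWrinkles = if (wr) sample(2:4, 1) else 0L,
        condensationLevel = runif(1, 0.2, 0.6),
        pixelSizeUm = pixelSizeUm,
        noiseGaussianSd = noiseGaussianSd,
        noisePoissonGain = noisePoissonGain,
        seed = sample.int(1000000000L, 1))
      ph <- makeNucleusPhantom(sp)
      out[[length(out) + 1L]] <- list(image = ph$image, truth = ph$truth,
                                      condition = cond, replicate = rep_)
    }
  }
  out
}

#' Forward-simulate a traction-force-microscopy bead image pair
#'
#' Builds a traction field as a sum of Gaussian patches (mean-subtracted so
#' the net force is exactly zero), computes the substrate surface
#' displacement with the Boussinesq elastic half-space Green tensor applied
#' spectrally, then renders fluorescent beads at subpixel centers via the
#' pixel-integrated Gaussian profile, once at rest and once displaced.
#'
#' @param patches data.frame with columns \code{xUm}, \code{yUm},
#'   \code{sigmaUm}, \code{txPa}, \code{tyPa}: Gaussian traction patches.
#' @param gel a \linkS4class{GelModel}.
#' @param fieldSizePx image side length (square field).
#' @param pixelSizeUm um per pixel.
#' @param beadDensity beads per px^2.
#' @param beadSigmaPx bead spot sd in pixels.
#' @param noiseGaussianSd additive image noise (0 = off).
#' @param seed RNG seed.
#' @return list: \code{reference}, \code{displaced} (matrices),
#'   \code{tractionTrue} (\linkS4class{TractionField} on the pixel grid),
#'   \code{displacementTrue} (\linkS4class{DisplacementField}), \code{gel}.
#' @export
makeTfmPair <- function(patches, gel, fieldSizePx = 256L, pixelSizeUm = 0.5,
                        beadDensity = 0.02, beadSigmaPx = 1.0,
                        noiseGaussianSd = 0, seed = 1L) {
  .assert(is(gel, "GelModel"), "gel must be a GelModel")
  n <- as.integer(fieldSizePx)
  L <- n * pixelSizeUm
  .assert(nrow(patches) == 0 || all(patches$sigmaUm * 6 < L),
          "traction patch wider than the field of view")
  xs <- (seq_len(n) - 1) * pixelSizeUm
  X <- matrix(xs, n, n, byrow = TRUE); Y <- matrix(xs, n, n)
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  if (nrow(patches) > 0) for (i in seq_len(nrow(patches))) {
    g <- exp(-((X - patches$xUm[i])^2 + (Y - patches$yUm[i])^2) /
               (2 * patches$sigmaUm[i]^2))
    tx <- tx + patches$txPa[i] * g
    ty <- ty + patches$tyPa[i] * g
  }
  tx <- tx - mean(tx); ty <- ty - mean(ty)   # enforce zero net force

  uu <- .halfspaceForward(tx, ty, gel@E, gel@nu, pixelSizeUm)

  set.seed(as.integer(seed))
  nBeads <- round(beadDensity * n * n)
  bx <- runif(nBeads, 4, n - 3); by <- runif(nBeads, 4, n - 3)
  ubx <- .bilinear(uu$ux, by, bx) / pixelSizeUm   # px displacement
  uby <- .bilinear(uu$uy, by, bx) / pixelSizeUm
  render <- function(cxs, cys) {
    img <- matrix(0, n, n)
    r <- ceiling(4 * beadSigmaPx)
    for (k in seq_len(nBeads)) {
      x0 <- round(cxs[k]); y0 <- round(cys[k])
      ix <- max(1, x0 - r):min(n, x0 + r)
      iy <- max(1, y0 - r):min(n, y0 + r)
      gx <- pnorm((ix + 0.5 - cxs[k]) / beadSigmaPx) -
            pnorm((ix - 0.5 - cxs[k]) / beadSigmaPx)
      gy <- pnorm((iy + 0.5 - cys[k]) / beadSigmaPx) -
            pnorm((iy - 0.5 - cys[k]) / beadSigmaPx)
      img[iy, ix] <- img[iy, ix] + outer(gy, gx)
    }
    img
  }
  ref <- render(bx, by)
  mov <- render(bx + ubx, by + uby)
  if (noiseGaussianSd > 0) {
    ref <- pmax(ref + rnorm(length(ref), 0, noiseGaussianSd), 0)
    mov <- pmax(mov + rnorm(length(mov), 0, noiseGaussianSd), 0)
  }
  tf <- new("TractionField", x = xs, y = xs, tx = tx, ty = ty, lambda = 0)
  df <- new("DisplacementField", x = xs, y = xs, ux = uu$ux, uy = uu$uy,
            quality = matrix(NA_real_, n, n),
            replaced = matrix(FALSE, n, n))
  list(reference = ref, displaced = mov, tractionTrue = tf,
       displacementTrue = df, gel = gel)
}

# Boussinesq half-space forward map, spectral: u(k) = G(k) T(k), with the
# standard in-plane Green tensor
#   G(k) = 2(1+nu) / (E k^3) * [ (1-nu)k^2 + nu ky^2,  -nu kx ky
#                                -nu kx ky,            (1-nu)k^2 + nu kx^2 ]
.halfspaceForward <- function(tx, ty, E, nu, pixelSizeUm) {
  n1 <- nrow(tx); n2 <- ncol(tx)
  kx <- 2 * pi * c(0:(floor(n2 / 2)), -(ceiling(n2 / 2) - 1):-1) /
    (n2 * pixelSizeUm)
  ky <- 2 * pi * c(0:(floor(n1 / 2)), -(ceiling(n1 / 2) - 1):-1) /
    (n1 * pixelSizeUm)
  KX <- matrix(kx, n1, n2, byrow = TRUE); KY <- matrix(ky, n1, n2)
  K <- sqrt(KX^2 + KY^2); K[1, 1] <- 1
  pref <- 2 * (1 + nu) / (E * K^3)
  Gxx <- pref * ((1 - nu) * K^2 + nu * KY^2)
  Gyy <- pref * ((1 - nu) * K^2 + nu * KX^2)
  Gxy <- -pref * nu * KX * KY
  Tx <- fft(tx); Ty <- fft(ty)
  Ux <- Gxx * Tx + Gxy * Ty
  Uy <- Gxy * Tx + Gyy * Ty
  Ux[1, 1] <- 0; Uy[1, 1] <- 0
  list(ux = Re(fft(Ux, inverse = TRUE)) / (n1 * n2),
       uy = Re(fft(Uy, inverse = TRUE)) / (n1 * n2))
}
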