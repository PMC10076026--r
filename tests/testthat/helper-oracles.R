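# Shared fixtures and independent oracles, built in code at test time.

# Closed analytic contour resampled to uniform arc length (points n x 2, um).
analyticContour <- function(fx, fy, n = 2000L, nDense = 8192L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = nDense + 1L)[-(nDense + 1L)]
  p <- cbind(fx(th), fy(th))
  pc <- rbind(p, p[1, ])
  s <- c(0, cumsum(sqrt(rowSums(diff(pc)^2))))
  L <- s[length(s)]
  sOut <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  pts <- cbind(approx(s, pc[, 1], xout = sOut)$y + center[1],
               approx(s, pc[, 2], xout = sOut)$y + center[2])
  Contour(pts, spacingUm = L / n)
}

circleContour <- function(r = 10, n = 2000L)
  analyticContour(function(t) r * cos(t), function(t) r * sin(t),
                  n = n, center = c(r + 2, r + 2))

ellipseContour <- function(a = 2, b = 1, n = 2000L)
  analyticContour(function(t) a * cos(t), function(t) b * sin(t),
                  n = n, center = c(a + 2, b + 2))

# Brute-force CCP oracle: explicit per-pixel replicate fill (two passes of
# mean-of-defined-8-neighbours), explicit 3x3 Sobel correlation loops,
# explicit threshold count. Independent of the package's vectorised path.
ccpOracle <- function(channel, mask, threshold) {
  nr <- nrow(channel); nc <- ncol(channel)
  f <- channel; f[!mask] <- 0
  def <- mask
  for (pass in 1:2) {
    f2 <- f; def2 <- def
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (def[i, j]) next
      s <- 0; cnt <- 0
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && def[ii, jj]) {
          s <- s + f[ii, jj]; cnt <- cnt + 1
        }
      }
      if (cnt > 0) { f2[i, j] <- s / cnt; def2[i, j] <- TRUE }
    }
    f <- f2; def <- def2
  }
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  edgeCount <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), nr); jj <- min(max(j + dj, 1), nc)
      gx <- gx + kx[di + 2, dj + 2] * f[ii, jj]
      gy <- gy + ky[di + 2, dj + 2] * f[ii, jj]
    }
    if (sqrt(gx^2 + gy^2) > threshold) edgeCount <- edgeCount + 1L
  }
  edgeCount / sum(mask)
}

# Textbook one-way ANOVA + Tukey HSD from first principles.
anovaOracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- k - 1; dfw <- N - k
  msb <- ssb / dfb; msw <- ssw / dfw
  Fv <- msb / msw
  p <- pf(Fv, dfb, dfw, lower.tail = FALSE)
  pairs <- combn(levels(groups), 2)
  tukey <- apply(pairs, 2, function(pr) {
    d <- means[pr[2]] - means[pr[1]]
    se <- sqrt(msw / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- abs(d) / se
    ptukey(q, k, dfw, lower.tail = FALSE)
  })
  list(F = Fv, p = p, tukeyP = unname(tukey),
       pairNames = apply(pairs, 2, function(pr) paste(pr[2], pr[1], sep = "-")))
}

# Integrated-Gaussian bead rendering (same profile the phantom generator
# uses) at arbitrary subpixel centers.
renderBeads <- function(bx, by, n, sigma = 1) {
  img <- matrix(0, n, n); r <- ceiling(4 * sigma)
  for (k in seq_along(bx)) {
    x0 <- round(bx[k]); y0 <- round(by[k])
    ix <- max(1, x0 - r):min(n, x0 + r)
    iy <- max(1, y0 - r):min(n, y0 + r)
    gx <- pnorm((ix + 0.5 - bx[k]) / sigma) - pnorm((ix - 0.5 - bx[k]) / sigma)
    gy <- pnorm((iy + 0.5 - by[k]) / sigma) - pnorm((iy - 0.5 - by[k]) / sigma)
    img[iy, ix] <- img[iy, ix] + outer(gy, gx)
  }
  img
}

# Empty patch table for traction-free bead pairs.
noPatches <- function()
  data.frame(xUm = numeric(0), yUm = numeric(0), sigmaUm = numeric(0),
             txPa = numeric(0), tyPa = numeric(0))

# Standard two-patch force dipole on a square field.
dipolePatches <- function(L, sigmaUm = 12, tPa = 2000)
  data.frame(xUm = c(0.3 * L, 0.7 * L), yUm = c(0.5 * L, 0.5 * L),
             sigmaUm = sigmaUm, txPa = c(tPa, -tPa), tyPa = 0)

# Subsample a fine-grid DisplacementField onto every `by`-th node.
subsampleField <- function(df, by, noiseSd = 0) {
  idx <- seq(by, length(df@x), by = by)
  m <- length(idx)
  ux <- df@ux[idx, idx]; uy <- df@uy[idx, idx]
  if (noiseSd > 0) {
    ux <- ux + rnorm(m * m, 0, noiseSd)
    uy <- uy + rnorm(m * m, 0, noiseSd)
  }
  new("DisplacementField", x = df@x[idx], y = df@y[idx], ux = ux, uy = uy,
      quality = matrix(NA_real_, m, m), replaced = matrix(FALSE, m, m))
}
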