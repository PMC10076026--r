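# Internal numeric helpers shared across modules. All operate on plain
# [y, x] matrices; EBImage is used where it provides the primitive.

#' @import methods
#' @importFrom stats fft sd quantile median approx aov TukeyHSD pf ptukey
#'   rbinom rnorm rpois runif cor dnorm pnorm mvfft
#' @importFrom grDevices contourLines
#' @importFrom utils head modifyList
NULL

# Shift a matrix by integer (dy, dx), replicating edge rows/columns.
.shiftMat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Gaussian blur with replicate boundary handling (EBImage's gblur uses
# circular wrap, which bleeds across image edges); separable convolution.
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- function(x, n, side) {
    if (side == "top") rbind(matrix(rep(x[1, ], each = n), nrow = n), x)
    else if (side == "bottom") rbind(x, matrix(rep(x[nrow(x), ], each = n), nrow = n))
    else if (side == "left") cbind(matrix(rep(x[, 1], times = n), ncol = n), x)
    else cbind(x, matrix(rep(x[, ncol(x)], times = n), ncol = n))
  }
  p <- pad(pad(m, r, "top"), r, "bottom")
  # convolve columns
  out <- apply(p, 2, function(col) stats::filter(col, k, sides = 2))
  out <- out[(r + 1):(r + nrow(m)), , drop = FALSE]
  p <- pad(pad(out, r, "left"), r, "right")
  out <- t(apply(p, 1, function(row) stats::filter(row, k, sides = 2)))
  out[, (r + 1):(r + ncol(m)), drop = FALSE]
}

# Otsu threshold on a numeric vector (maximises between-class variance on a
# fixed-bin histogram). Needed for thresholds restricted to in-mask values;
# EBImage's otsu() only operates on whole images.
.otsuVec <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  br <- seq(lo, hi, length.out = nbins + 1L)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), nbins), nbins)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  w <- cumsum(h); mu <- cumsum(h * mids)
  tot <- w[nbins]; mtot <- mu[nbins]
  w1 <- w[-nbins]; w2 <- tot - w1
  m1 <- mu[-nbins] / w1; m2 <- (mtot - mu[-nbins]) / w2
  bc <- w1 * w2 * (m1 - m2)^2
  bc[!is.finite(bc)] <- -Inf
  mids[which.max(bc)]
}

# Periodic (circular) Gaussian smoothing of a closed sequence sampled at
# uniform arc spacing h, via FFT.
.circSmooth <- function(x, sigma, h) {
  n <- length(x)
  if (sigma <= 0 || n < 4) return(x)
  d <- (seq_len(n) - 1)
  d <- pmin(d, n - d) * h
  k <- exp(-d^2 / (2 * sigma^2))
  k <- k / sum(k)
  Re(fft(fft(x) * fft(k), inverse = TRUE)) / n
}

# Zhang-Suen thinning of a logical matrix down to a 1-px-wide skeleton.
# EBImage ships no skeletonization, so this is implemented here.
.thinZS <- function(m) {
  img <- m * 1L
  nb <- function(img) {
    list(p2 = .shiftMat(img,  1,  0), p3 = .shiftMat(img,  1, -1),
         p4 = .shiftMat(img,  0, -1), p5 = .shiftMat(img, -1, -1),
         p6 = .shiftMat(img, -1,  0), p7 = .shiftMat(img, -1,  1),
         p8 = .shiftMat(img,  0,  1), p9 = .shiftMat(img,  1,  1))
  }
  # note: .shiftMat replicates edges; zero the border to avoid artefacts
  img[1, ] <- 0L; img[nrow(img), ] <- 0L; img[, 1] <- 0L; img[, ncol(img)] <- 0L
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      n <- nb(img)
      B <- n$p2 + n$p3 + n$p4 + n$p5 + n$p6 + n$p7 + n$p8 + n$p9
      seqs <- list(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9, n$p2)
      A <- matrix(0L, nrow(img), ncol(img))
      for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (pass == 1) {
        c1 <- n$p2 * n$p4 * n$p6; c2 <- n$p4 * n$p6 * n$p8
      } else {
        c1 <- n$p2 * n$p4 * n$p8; c2 <- n$p2 * n$p6 * n$p8
      }
      del <- img == 1L & B >= 2 & B <= 6 & A == 1L & c1 == 0L & c2 == 0L
      if (any(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1L
}

# Polyline length of a 1-px skeleton: orthogonal neighbour pairs count 1,
# diagonal pairs sqrt(2) unless they short-cut an orthogonal staircase.
.skeletonLengthPx <- function(sk) {
  if (!any(sk)) return(0)
  s <- sk * 1L
  o <- sum(s[-1, ] * s[-nrow(s), ]) + sum(s[, -1] * s[, -ncol(s)])
  d1 <- s[-1, -1] * s[-nrow(s), -ncol(s)]          # (y,x) with (y+1,x+1)
  d2 <- s[-1, -ncol(s)] * s[-nrow(s), -1]          # (y,x+1) with (y+1,x)
  # drop diagonals whose corner 4-neighbour is also set (staircase shortcut)
  c1 <- s[-1, -ncol(s)] | s[-nrow(s), -1]
  c2 <- s[-1, -1] | s[-nrow(s), -ncol(s)]
  nd <- sum(d1 * (1 - c1)) + sum(d2 * (1 - c2))
  o + sqrt(2) * nd
}

# Bilinear sampling of matrix m at fractional (y, x) positions (1-based),
# replicate outside.
.bilinear <- function(m, y, x) {
  nr <- nrow(m); nc <- ncol(m)
  y <- as.vector(y); x <- as.vector(x)
  y <- pmin(pmax(y, 1), nr); x <- pmin(pmax(x, 1), nc)
  y0 <- pmin(floor(y), nr - 1); x0 <- pmin(floor(x), nc - 1)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  m[i00] * (1 - fy) * (1 - fx) + m[i01] * (1 - fy) * fx +
    m[i10] * fy * (1 - fx) + m[i11] * fy * fx
}

# 3-point Gaussian sub-sample peak refinement; values must be positive.
.gauss3 <- function(cm, c0, cp) {
  eps <- 1e-12
  cm <- max(cm, eps); c0 <- max(c0, eps); cp <- max(cp, eps)
  den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
  if (abs(den) < eps) return(0)
  off <- (log(cm) - log(cp)) / den
  if (!is.finite(off) || abs(off) > 1) 0 else off
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# derive an independent RNG substream seed without integer overflow
.substreamSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}
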