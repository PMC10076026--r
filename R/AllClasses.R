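#' ImageStack: a calibrated multi-channel microscopy image
#'
#' Canonical container for 2D planes and 3D z-stacks. Pixel data are stored
#' as a 4D array with the package-wide axis order \code{(y, x, channel, z)}
#' (singleton channel/z axes are kept so every image has the same layout).
#' Pixel indices are 0-based with pixel centers at integer coordinates;
#' physical units are micrometres.
#'
#' @slot pixels 4D numeric array, dim \code{(ny, nx, nChannels, nz)};
#'   finite, non-negative intensities in arbitrary units.
#' @slot channelNames character vector, one label per channel
#'   (e.g. \code{"DAPI"}, \code{"lamin"}).
#' @slot pixelSizeUm positive scalar, micrometres per pixel in x and y.
#' @slot zStepUm micrometres between planes; \code{NA_real_} for 2D.
#'
#' @examples
#' img <- ImageStack(matrix(runif(64), 8, 8), channelNames = "DAPI",
#'                   pixelSizeUm = 0.2)
#' pixelSize(img)
#' @export
setClass("ImageStack",
  representation(pixels = "array", channelNames = "character",
                 pixelSizeUm = "numeric", zStepUm = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 4L) return("pixels must be a 4D (y, x, channel, z) array")
    if (!all(is.finite(p))) return("all intensities must be finite")
    if (any(p < 0)) return("all intensities must be >= 0")
    if (any(dim(p) == 0L)) return("zero-size image")
    if (dim(p)[3] != length(object@channelNames))
      return("channel count must match channelNames length")
    if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
        object@pixelSizeUm <= 0) return("pixelSizeUm must be a positive scalar")
    if (dim(p)[4] > 1L && (is.na(object@zStepUm) || object@zStepUm <= 0))
      return("zStepUm must be > 0 for a 3D stack")
    TRUE
  })

#' Construct an ImageStack
#'
#' Accepts a matrix (single 2D plane), a 3D array interpreted as
#' \code{(y, x, channel)}, or a full \code{(y, x, channel, z)} array.
#'
#' @param pixels matrix or array of non-negative intensities.
#' @param channelNames character vector of channel labels.
#' @param pixelSizeUm micrometres per pixel (x and y).
#' @param zStepUm micrometres between z-planes (3D stacks only).
#' @return An \linkS4class{ImageStack}.
#' @export
ImageStack <- function(pixels, channelNames = "ch1", pixelSizeUm = 1,
                       zStepUm = NA_real_) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L, 1L)
  else if (length(dim(pixels)) == 3L) dim(pixels) <- c(dim(pixels), 1L)
  new("ImageStack", pixels = pixels, channelNames = channelNames,
      pixelSizeUm = pixelSizeUm, zStepUm = zStepUm)
}

#' Contour: closed subpixel nuclear boundary
#'
#' An ordered, closed, simple polyline in physical coordinates (micrometres),
#' stored without the repeated closing vertex and resampled to uniform
#' arc-length spacing. Orientation is counterclockwise: the signed
#' (shoelace) area is positive, and with the package's curvature sign
#' convention locally convex (outward-bulging) boundary has positive
#' curvature.
#'
#' @slot points n x 2 matrix of (x, y) vertex positions in micrometres.
#' @slot spacingUm uniform arc-length spacing between consecutive vertices.
#' @export
setClass("Contour",
  representation(points = "matrix", spacingUm = "numeric"),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 2L) return("points must be n x 2")
    if (nrow(p) < 16L) return("contour must have >= 16 vertices")
    if (!all(is.finite(p))) return("contour points must be finite")
    if (.shoelace(p) <= 0) return("contour must be counterclockwise (signed area > 0)")
    TRUE
  })

# signed polygon area (shoelace), closed implicitly
.shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' @describeIn Contour constructor; reverses clockwise input to enforce the
#'   counterclockwise convention.
#' @param points n x 2 matrix of (x, y) vertices in micrometres (closed
#'   polyline; a repeated last vertex is dropped).
#' @param spacingUm arc-length spacing in micrometres.
#' @export
Contour <- function(points, spacingUm) {
  if (nrow(points) > 1 && all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  if (.shoelace(points) < 0) points <- points[nrow(points):1, , drop = FALSE]
  colnames(points) <- c("x", "y")
  new("Contour", points = points, spacingUm = spacingUm)
}

#' NucleusMask: one segmented nucleus
#'
#' @slot label integer id within the source image.
#' @slot mask logical full-frame matrix, one filled connected component.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot planeOfFocus z index the 2D measures refer to.
#' @export
setClass("NucleusMask",
  representation(label = "integer", mask = "matrix",
                 pixelSizeUm = "numeric", planeOfFocus = "integer"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!any(object@mask)) return("mask is empty")
    TRUE
  })

#' CurvatureProfile: signed curvature along a closed contour
#'
#' Curvature is in 1/micrometre; positive means locally convex under the
#' counterclockwise orientation, so boundary invaginations appear as
#' contiguous negative-curvature arcs. For any simple closed contour the
#' total turning \eqn{\sum \kappa \, \Delta s} equals \eqn{2\pi}.
#'
#' @slot arcPositions arc-length position (um) of each vertex.
#' @slot kappa signed curvature (1/um) per vertex.
#' @slot smoothSigmaUm Gaussian coordinate-smoothing scale used (um).
#' @slot perimeterUm contour perimeter (um).
#' @slot areaUm2 enclosed area (um^2).
#' @export
setClass("CurvatureProfile",
  representation(arcPositions = "numeric", kappa = "numeric",
                 smoothSigmaUm = "numeric", perimeterUm = "numeric",
                 areaUm2 = "numeric"),
  validity = function(object) {
    if (length(object@arcPositions) != length(object@kappa))
      return("arcPositions and kappa lengths differ")
    if (!all(is.finite(object@kappa))) return("kappa must be finite everywhere")
    TRUE
  })

#' InvaginationCall: negative-curvature runs on one contour
#'
#' @slot runs data.frame with columns \code{startUm}, \code{endUm},
#'   \code{minKappa}, \code{lengthUm}; disjoint and ordered by start.
#' @slot invaginated logical; \code{TRUE} iff at least one run passed the
#'   depth and length thresholds.
#' @slot kappaMin curvature threshold used (1/um).
#' @slot lenMinUm minimum run arc length used (um).
#' @export
setClass("InvaginationCall",
  representation(runs = "data.frame", invaginated = "logical",
                 kappaMin = "numeric", lenMinUm = "numeric"))

#' WrinkleResult: surface ridge (wrinkle) score for one nucleus
#'
#' @slot ridgeLengthDensity um of ridge centerline per um^2 of (eroded)
#'   nuclear area.
#' @slot wrinkled logical call at the configured density threshold.
#' @slot skeleton logical matrix of ridge centerline pixels.
#' @slot densityMin threshold used for the binary call.
#' @export
setClass("WrinkleResult",
  representation(ridgeLengthDensity = "numeric", wrinkled = "logical",
                 skeleton = "matrix", densityMin = "numeric"),
  validity = function(object) {
    if (object@ridgeLengthDensity < 0) return("density must be >= 0")
    if (object@ridgeLengthDensity == 0 && object@wrinkled)
      return("zero density cannot be wrinkled")
    TRUE
  })

#' CCPResult: chromatin condensation parameter for one nucleus
#'
#' CCP is the number of Sobel edge pixels inside the nucleus divided by the
#' nuclear cross-sectional area in pixels, a dimensionless edge density in
#' [0, 1]. Higher CCP means more condensed (less accessible) chromatin.
#' Because the normalisation is per pixel, CCP depends on magnification:
#' compare values only at a fixed pixel size.
#'
#' @slot ccp edge density in [0, 1]; exactly edgePixelCount / areaPx.
#' @slot edgePixelCount integer count of supra-threshold gradient pixels.
#' @slot areaPx integer nuclear area in pixels.
#' @slot edgeMap logical matrix (subset of the nucleus mask).
#' @slot thresholdUsed gradient-magnitude cutoff applied.
#' @slot thresholdRule rule that produced the cutoff.
#' @export
setClass("CCPResult",
  representation(ccp = "numeric", edgePixelCount = "integer",
                 areaPx = "integer", edgeMap = "matrix",
                 thresholdUsed = "numeric", thresholdRule = "character"),
  validity = function(object) {
    if (object@areaPx <= 0L) return("areaPx must be positive")
    if (object@ccp < 0 || object@ccp > 1) return("ccp must be in [0, 1]")
    if (abs(object@ccp - object@edgePixelCount / object@areaPx) > 1e-12)
      return("ccp must equal edgePixelCount / areaPx")
    TRUE
  })

#' GelModel: linear-elastic substrate parameters
#'
#' @slot E Young's modulus in Pa.
#' @slot nu Poisson ratio (0.5 = incompressible, the polyacrylamide
#'   convention).
#' @export
setClass("GelModel",
  representation(E = "numeric", nu = "numeric"),
  validity = function(object) {
    if (object@E <= 0) return("E must be > 0")
    if (object@nu < 0 || object@nu > 0.5) return("nu must be in [0, 0.5]")
    TRUE
  })

#' @describeIn GelModel constructor.
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @export
GelModel <- function(E, nu = 0.5) new("GelModel", E = E, nu = nu)

#' DisplacementField: gridded substrate displacement
#'
#' @slot x,y grid node coordinates (um), strictly increasing, uniform.
#' @slot ux,uy displacement components (um) as \code{length(y) x length(x)}
#'   matrices.
#' @slot quality per-node correlation quality (peak ratio); NA where not
#'   applicable.
#' @slot replaced logical matrix marking vectors replaced by the median of
#'   their neighbours.
#' @export
setClass("DisplacementField",
  representation(x = "numeric", y = "numeric", ux = "matrix", uy = "matrix",
                 quality = "matrix", replaced = "matrix"),
  validity = function(object) {
    if (!all(is.finite(object@ux)) || !all(is.finite(object@uy)))
      return("displacement vectors must be finite")
    if (length(object@x) < 2 || length(object@y) < 2) return("grid too small")
    dx <- diff(object@x); dy <- diff(object@y)
    if (any(dx <= 0) || any(dy <= 0)) return("grid coordinates must increase")
    if (max(abs(dx - dx[1])) > 1e-6 * dx[1] ||
        max(abs(dy - dy[1])) > 1e-6 * dy[1])
      return("grid spacing must be uniform")
    TRUE
  })

#' TractionField: gridded traction stress (Pa)
#'
#' @slot x,y grid node coordinates (um).
#' @slot tx,ty traction components (Pa) as \code{length(y) x length(x)}
#'   matrices; spatial mean is zero by construction (no net force).
#' @slot lambda Tikhonov regularisation parameter used.
#' @export
setClass("TractionField",
  representation(x = "numeric", y = "numeric", tx = "matrix", ty = "matrix",
                 lambda = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@tx)) || !all(is.finite(object@ty)))
      return("traction must be finite")
    mx <- sqrt(mean(object@tx)^2 + mean(object@ty)^2)
    pk <- max(sqrt(object@tx^2 + object@ty^2))
    if (pk > 0 && mx > 1e-6 * pk) return("net force must vanish")
    TRUE
  })

#' PhantomSpec: parameters of one synthetic nucleus image
#'
#' The generator draws a DAPI-like channel bounded by an ellipse with
#' \code{nInvaginations} inward cosine-bump lobes (each yielding exactly one
#' contiguous negative-curvature arc), a lamin-like shell channel carrying
#' \code{nWrinkles} dark Gaussian-profile ridge folds across the interior,
#' and interior chromatin texture whose edge density increases strictly
#' with \code{condensationLevel}. Identical spec + seed gives bit-identical
#' pixels.
#'
#' @slot a,b ellipse semi-axes (um); \code{c} third semi-axis (um,
#'   \code{NA} for 2D).
#' @slot nInvaginations integer >= 0 lobes.
#' @slot invaginationDepth lobe depth as a fraction of the equivalent
#'   radius, in (0, 1).
#' @slot invaginationWidth angular lobe extent (radians).
#' @slot nWrinkles integer >= 0 ridge folds.
#' @slot condensationLevel chromatin texture level in [0, 1].
#' @slot ncEnrichment nuclear / cytoplasmic intensity factor of the marker
#'   channel.
#' @slot pixelSizeUm,zStepUm sampling (um).
#' @slot noiseGaussianSd additive read-noise sd (intensity units; 0 = off).
#' @slot noisePoissonGain photons per intensity unit for shot noise
#'   (0 = off).
#' @slot seed RNG seed.
#' @export
setClass("PhantomSpec",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 nInvaginations = "integer", invaginationDepth = "numeric",
                 invaginationWidth = "numeric", nWrinkles = "integer",
                 condensationLevel = "numeric", ncEnrichment = "numeric",
                 pixelSizeUm = "numeric", zStepUm = "numeric",
                 noiseGaussianSd = "numeric", noisePoissonGain = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@a <= 0 || object@b <= 0) return("semi-axes must be > 0")
    if (!is.na(object@c) && object@c <= 0) return("c must be > 0 when 3D")
    if (object@nInvaginations < 0L) return("nInvaginations must be >= 0")
    if (object@nInvaginations > 0L &&
        (object@invaginationDepth <= 0 || object@invaginationDepth >= 1))
      return("invaginationDepth must be in (0, 1)")
    if (object@condensationLevel < 0 || object@condensationLevel > 1)
      return("condensationLevel must be in [0, 1]")
    if (object@nInvaginations > 0L &&
        object@invaginationWidth * object@nInvaginations >= 2 * pi)
      return("lobes overlap: nInvaginations * invaginationWidth must be < 2*pi")
    if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
    TRUE
  })

#' @describeIn PhantomSpec constructor with documented defaults. The default
#'   geometry (semi-axes 8 x 6 um, 0.1 um pixels) mimics a spread-cell
#'   nucleus at high-magnification sampling; noise is off by default so the
#'   generator can serve as an exact oracle.
#' @param a,b,c ellipse semi-axes (um); omit \code{c} for a 2D phantom.
#' @param nInvaginations,invaginationDepth,invaginationWidth lobe geometry.
#' @param nWrinkles number of ridge folds.
#' @param condensationLevel chromatin texture level in [0, 1].
#' @param ncEnrichment marker nuclear enrichment factor.
#' @param pixelSizeUm,zStepUm sampling (um).
#' @param noiseGaussianSd,noisePoissonGain noise model (0 = off).
#' @param seed RNG seed (integer).
#' @export
PhantomSpec <- function(a = 8, b = 6, c = NA_real_, nInvaginations = 0L,
                        invaginationDepth = 0.3, invaginationWidth = 1.1,
                        nWrinkles = 0L, condensationLevel = 0,
                        ncEnrichment = 2, pixelSizeUm = 0.1, zStepUm = 0.2,
                        noiseGaussianSd = 0, noisePoissonGain = 0,
                        seed = 1L) {
  new("PhantomSpec", a = a, b = b, c = c,
      nInvaginations = as.integer(nInvaginations),
      invaginationDepth = invaginationDepth,
      invaginationWidth = invaginationWidth,
      nWrinkles = as.integer(nWrinkles),
      condensationLevel = condensationLevel, ncEnrichment = ncEnrichment,
      pixelSizeUm = pixelSizeUm, zStepUm = zStepUm,
      noiseGaussianSd = noiseGaussianSd, noisePoissonGain = noisePoissonGain,
      seed = as.integer(seed))
}
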