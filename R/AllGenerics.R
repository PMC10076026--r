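# Generics and accessor/show methods for the core classes.

#' Accessors for ImageStack
#'
#' @param object an \linkS4class{ImageStack}.
#' @return \code{pixelSize}: um/pixel; \code{zStep}: um between planes
#'   (\code{NA} for 2D); \code{channelNames}: channel labels; \code{nPlanes}:
#'   number of z-planes; \code{isStack3D}: logical.
#' @name ImageStack-accessors
NULL

#' @rdname ImageStack-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname ImageStack-accessors
#' @export
setMethod("pixelSize", "ImageStack", function(object) object@pixelSizeUm)

#' @rdname ImageStack-accessors
#' @export
setGeneric("zStep", function(object) standardGeneric("zStep"))
#' @rdname ImageStack-accessors
#' @export
setMethod("zStep", "ImageStack", function(object) object@zStepUm)

#' @rdname ImageStack-accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname ImageStack-accessors
#' @export
setMethod("channelNames", "ImageStack", function(object) object@channelNames)

#' @rdname ImageStack-accessors
#' @export
setGeneric("nPlanes", function(object) standardGeneric("nPlanes"))
#' @rdname ImageStack-accessors
#' @export
setMethod("nPlanes", "ImageStack", function(object) dim(object@pixels)[4])

#' @rdname ImageStack-accessors
#' @export
setGeneric("isStack3D", function(object) standardGeneric("isStack3D"))
#' @rdname ImageStack-accessors
#' @export
setMethod("isStack3D", "ImageStack", function(object) dim(object@pixels)[4] > 1L)

#' Extract one channel of an ImageStack
#'
#' @param object an \linkS4class{ImageStack}.
#' @param channel channel name or index.
#' @param z z-plane index, or \code{"max"} for the maximum-intensity
#'   projection over z.
#' @return numeric \code{(y, x)} matrix.
#' @export
setGeneric("getChannel", function(object, channel = 1L, z = 1L)
  standardGeneric("getChannel"))

#' @rdname getChannel
#' @export
setMethod("getChannel", "ImageStack", function(object, channel = 1L, z = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, object@channelNames)
    .assert(!is.na(channel), "unknown channel name")
  }
  if (identical(z, "max"))
    return(apply(object@pixels[, , channel, , drop = FALSE], c(1, 2), max))
  object@pixels[, , channel, z]
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageStack: %d x %d px, %d channel(s) [%s], %d plane(s)\n",
              d[1], d[2], d[3], paste(object@channelNames, collapse = ", "),
              d[4]))
  cat(sprintf("  pixel size %.4g um%s\n", object@pixelSizeUm,
              if (d[4] > 1) sprintf(", z-step %.4g um", object@zStepUm) else ""))
})

#' Contour accessors
#'
#' @param object a \linkS4class{Contour}.
#' @return \code{contourPoints}: n x 2 (x, y) matrix (um);
#'   \code{perimeter}: total arc length (um); \code{enclosedArea}:
#'   shoelace area (um^2).
#' @name Contour-accessors
NULL

#' @rdname Contour-accessors
#' @export
setGeneric("contourPoints", function(object) standardGeneric("contourPoints"))
#' @rdname Contour-accessors
#' @export
setMethod("contourPoints", "Contour", function(object) object@points)

#' @rdname Contour-accessors
#' @export
setGeneric("perimeter", function(object) standardGeneric("perimeter"))
#' @rdname Contour-accessors
#' @export
setMethod("perimeter", "Contour", function(object) {
  p <- object@points
  p2 <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((p2 - p)^2)))
})

#' @rdname Contour-accessors
#' @export
setGeneric("enclosedArea", function(object) standardGeneric("enclosedArea"))
#' @rdname Contour-accessors
#' @export
setMethod("enclosedArea", "Contour", function(object) .shoelace(object@points))

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour: %d vertices, perimeter %.2f um, area %.2f um^2\n",
              nrow(object@points), perimeter(object), enclosedArea(object)))
})

setMethod("show", "CurvatureProfile", function(object) {
  cat(sprintf(
    "CurvatureProfile: %d vertices, kappa in [%.3f, %.3f] 1/um, turning %.4f*2pi\n",
    length(object@kappa), min(object@kappa), max(object@kappa),
    sum(object@kappa * diff(c(object@arcPositions,
                              object@perimeterUm))) / (2 * pi)))
})

setMethod("show", "CCPResult", function(object) {
  cat(sprintf("CCPResult: CCP = %.4f (%d edge px / %d px, %s threshold %.4g)\n",
              object@ccp, object@edgePixelCount, object@areaPx,
              object@thresholdRule, object@thresholdUsed))
})

setMethod("show", "InvaginationCall", function(object) {
  cat(sprintf("InvaginationCall: %s (%d run(s), kappaMin %.3f, Lmin %.2f um)\n",
              if (object@invaginated) "invaginated" else "not invaginated",
              nrow(object@runs), object@kappaMin, object@lenMinUm))
})

setMethod("show", "WrinkleResult", function(object) {
  cat(sprintf("WrinkleResult: density %.4f um/um^2 -> %s (threshold %.4f)\n",
              object@ridgeLengthDensity,
              if (object@wrinkled) "wrinkled" else "not wrinkled",
              object@densityMin))
})

setMethod("show", "DisplacementField", function(object) {
  mag <- sqrt(object@ux^2 + object@uy^2)
  cat(sprintf("DisplacementField: %d x %d grid, |u| max %.3f um, spacing %.3f um\n",
              length(object@y), length(object@x), max(mag),
              object@x[2] - object@x[1]))
})

setMethod("show", "TractionField", function(object) {
  mag <- sqrt(object@tx^2 + object@ty^2)
  cat(sprintf("TractionField: %d x %d grid, |T| max %.1f Pa, lambda %.3g\n",
              length(object@y), length(object@x), max(mag), object@lambda))
})

setMethod("show", "GelModel", function(object) {
  cat(sprintf("GelModel: E = %.4g Pa, nu = %.2f\n", object@E, object@nu))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s ellipse %.3g x %.3g um, %d lobe(s) (depth %.2f), %d wrinkle(s), condensation %.2f, seed %d\n",
    if (is.na(object@c)) "2D" else "3D", object@a, object@b,
    object@nInvaginations, object@invaginationDepth, object@nWrinkles,
    object@condensationLevel, object@seed))
})
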