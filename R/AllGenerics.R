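#' Accessors for orrpipe classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an orrpipe S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("channelRole", function(object) standardGeneric("channelRole"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))
#' @rdname accessors
#' @export
setGeneric("nPlanes", function(object) standardGeneric("nPlanes"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("nObjects", function(object) standardGeneric("nObjects"))
#' @rdname accessors
#' @export
setGeneric("orrValues", function(object) standardGeneric("orrValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("crosstalkAlpha", function(object) standardGeneric("crosstalkAlpha"))

#' @rdname accessors
setMethod("pixels", "ChannelStack", function(object) object@pixels)
#' @rdname accessors
setMethod("pixels", "SummedImage", function(object) object@pixels)
#' @rdname accessors
setMethod("channelRole", "ChannelStack", function(object) object@channelRole)
#' @rdname accessors
setMethod("channelRole", "SummedImage", function(object) object@channelRole)
#' @rdname accessors
setMethod("pixelSizeUm", "ChannelStack", function(object) object@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSizeUm", "SummedImage", function(object) object@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSizeUm", "LabelMap", function(object) object@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSizeUm", "RedoxMap", function(object) object@pixelSizeUm)
#' @rdname accessors
setMethod("nPlanes", "ChannelStack", function(object) dim(object@pixels)[1])
#' @rdname accessors
setMethod("nPlanes", "SummedImage", function(object) object@nPlanesSummed)
#' @rdname accessors
setMethod("labelMatrix", "LabelMap", function(object) object@labels)
#' @rdname accessors
setMethod("nObjects", "LabelMap", function(object) object@nObjects)
#' @rdname accessors
setMethod("orrValues", "RedoxMap", function(object) object@orr)
#' @rdname accessors
setMethod("validMask", "RedoxMap", function(object) object@valid)
#' @rdname accessors
setMethod("crosstalkAlpha", "CrosstalkCalibration", function(object) object@alpha)

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ChannelStack [%s]: %d plane(s) of %d x %d, pixel %.4g um\n",
              object@channelRole, d[1], d[2], d[3], object@pixelSizeUm))
})

setMethod("show", "AcquisitionSet", function(object) {
  d <- dim(object@brightfield@pixels)
  cat(sprintf(
    "AcquisitionSet '%s': %d x %d px, FOV %.2f um, channels: brightfield (%d pl), nadph (%d pl), fad (%d pl)\n",
    object@fieldId, d[2], d[3], object@fovUm,
    dim(object@brightfield@pixels)[1], dim(object@nadph@pixels)[1],
    dim(object@fad@pixels)[1]))
})

setMethod("show", "SummedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SummedImage [%s]: %d x %d, sum of %d plane(s), range [%g, %g]\n",
              object@channelRole, d[1], d[2], object@nPlanesSummed,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap: %d object(s) in %d x %d raster\n",
              object@nObjects, nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "RedoxMap", function(object) {
  v <- object@orr[object@valid]
  cat(sprintf("RedoxMap: %d x %d, %d valid pixel(s)%s\n",
              nrow(object@orr), ncol(object@orr), sum(object@valid),
              if (length(v)) sprintf(", median ORR %.3f", median(v)) else ""))
})

setMethod("show", "BackgroundEstimate", function(object) {
  cat(sprintf("BackgroundEstimate [%s]: %.4g over %d background pixel(s)\n",
              object@channelRole, object@value, object@nBackgroundPixels))
})

setMethod("show", "CrosstalkCalibration", function(object) {
  cat(sprintf(
    "CrosstalkCalibration: alpha = %.4f (stderr %.4g), %d well(s), range %.3g-%.3g mM\n",
    object@alpha, object@fitStderr, object@nPoints,
    object@concentrationRangeMM[1], object@concentrationRangeMM[2]))
})

setMethod("show", "TileGrid", function(object) {
  cat(sprintf("TileGrid: %d x %d cells, %d placed tile(s) of %d x %d px\n",
              object@rows, object@cols, nrow(object@placement),
              object@tileShape[1], object@tileShape[2]))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s): omnibus p = %.4g\n",
              object@pathTaken, object@omnibusP))
  if (nrow(object@pairwise)) {
    p <- object@pairwise
    for (i in seq_len(nrow(p)))
      cat(sprintf("  %s vs %s: p_adj = %.4g %s\n", p$group1[i], p$group2[i],
                  p$p_adjusted[i], p$stars[i]))
  }
})

setMethod("show", "SizeOrrFit", function(object) {
  cat(sprintf("SizeOrrFit: slope %.3g ORR/um^2, intercept %.3g, r = %.3f, n = %d\n",
              object@slope, object@intercept, object@r, object@n))
})

setMethod("show", "PhenotypePreset", function(object) {
  cat(sprintf(
    "PhenotypePreset '%s': median ORR %.2f (spread %.2f), rim boost %.2f, radius %g-%g um, %d object(s)\n",
    object@name, object@trueMedianOrr, object@orrSpread,
    object@peripheryBoost, object@objectRadiusUm[1],
    object@objectRadiusUm[2], object@nObjects))
})
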