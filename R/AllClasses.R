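#' @import methods
#' @importFrom stats median quantile rnorm rpois runif sd aov kruskal.test
#'   pchisq pnorm p.adjust coef lm cor complete.cases setNames pairwise.t.test
#' @importFrom utils write.csv read.csv packageVersion
NULL

.CHANNEL_ROLES <- c("brightfield", "nadph", "fad", "other")

#' ChannelStack: one channel's z-stack of co-registered intensity rasters
#'
#' Container for a single acquisition channel: a (z, y, x) stack of
#' non-negative intensities plus the acquisition metadata needed downstream.
#' The z planes are repeated scans over a shallow (0.1 um step) stack and are
#' treated as co-registered.
#'
#' @slot pixels numeric 3D array, dimensions (z, y, x), all values >= 0.
#' @slot channelRole one of \code{"brightfield"}, \code{"nadph"} (440 +/- 20 nm
#'   detection band), \code{"fad"} (520 +/- 20 nm band) or \code{"other"}.
#' @slot zStepUm z step between planes in micrometres.
#' @slot pixelSizeUm lateral pixel size in micrometres (> 0).
#' @slot bitDepth integer bit depth of the source data.
#' @exportClass ChannelStack
setClass("ChannelStack",
  representation(
    pixels = "array",
    channelRole = "character",
    zStepUm = "numeric",
    pixelSizeUm = "numeric",
    bitDepth = "integer"
  )
)

setValidity("ChannelStack", function(object) {
  msg <- character()
  if (length(dim(object@pixels)) != 3L)
    msg <- c(msg, "pixels must be a 3D (z, y, x) array")
  if (any(object@pixels < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative")
  if (!(object@channelRole %in% .CHANNEL_ROLES))
    msg <- c(msg, sprintf("channelRole must be one of: %s",
                          paste(.CHANNEL_ROLES, collapse = ", ")))
  if (!is.na(object@pixelSizeUm) && object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' AcquisitionSet: the bright-field / NAD(P)H / FAD triple for one field
#'
#' @slot brightfield,nadph,fad \linkS4class{ChannelStack} objects sharing
#'   (y, x) shape and pixel size.
#' @slot fieldId identifier of the field of view.
#' @slot fovUm field-of-view width in micrometres (the reference system uses
#'   a 1272.32 x 1272.32 um^2 field).
#' @exportClass AcquisitionSet
setClass("AcquisitionSet",
  representation(
    brightfield = "ChannelStack",
    nadph = "ChannelStack",
    fad = "ChannelStack",
    fieldId = "character",
    fovUm = "numeric"
  )
)

setValidity("AcquisitionSet", function(object) {
  msg <- character()
  shp <- function(cs) dim(cs@pixels)[2:3]
  if (!identical(shp(object@brightfield), shp(object@nadph)) ||
      !identical(shp(object@brightfield), shp(object@fad)))
    msg <- c(msg, "all three stacks must share (y, x) shape")
  ps <- c(object@brightfield@pixelSizeUm, object@nadph@pixelSizeUm,
          object@fad@pixelSizeUm)
  if (any(abs(ps - ps[1]) > 1e-9 * ps[1], na.rm = TRUE))
    msg <- c(msg, "all three stacks must share pixelSizeUm")
  if (!is.na(object@fovUm)) {
    width <- shp(object@brightfield)[2]
    if (abs(object@fovUm - ps[1] * width) > 1e-6 * object@fovUm)
      msg <- c(msg, "fovUm must equal pixelSizeUm * image width")
  }
  if (length(msg)) msg else TRUE
})

#' SummedImage: a z-stack collapsed by per-pixel summation
#'
#' The wide-accumulator 2D image obtained by summing all planes of a
#' \linkS4class{ChannelStack}; summation (rather than averaging) preserves the
#' integer character of count data while raising the signal-to-noise ratio.
#'
#' @slot pixels numeric matrix (y, x) of non-negative sums.
#' @slot channelRole channel role inherited from the stack.
#' @slot pixelSizeUm lateral pixel size (um).
#' @slot nPlanesSummed number of planes summed (>= 1).
#' @exportClass SummedImage
setClass("SummedImage",
  representation(
    pixels = "matrix",
    channelRole = "character",
    pixelSizeUm = "numeric",
    nPlanesSummed = "integer"
  )
)

setValidity("SummedImage", function(object) {
  msg <- character()
  if (any(object@pixels < 0, na.rm = TRUE))
    msg <- c(msg, "summed intensities must be non-negative")
  if (object@nPlanesSummed < 1L)
    msg <- c(msg, "nPlanesSummed must be >= 1")
  if (length(msg)) msg else TRUE
})

#' LabelMap: indexed object mask
#'
#' Integer raster assigning every pixel to background (0) or to one of K
#' connected objects labelled 1..K in deterministic raster-scan order of the
#' first-encountered pixel.
#'
#' @slot labels integer matrix, 0 = background, 1..K = objects.
#' @slot nObjects K.
#' @slot pixelSizeUm lateral pixel size (um).
#' @exportClass LabelMap
setClass("LabelMap",
  representation(
    labels = "matrix",
    nObjects = "integer",
    pixelSizeUm = "numeric"
  )
)

setValidity("LabelMap", function(object) {
  msg <- character()
  K <- object@nObjects
  lv <- sort(unique(as.integer(object@labels)))
  lv <- lv[lv != 0L]
  if (!identical(lv, if (K > 0L) seq_len(K) else integer(0)))
    msg <- c(msg, "labels must be contiguous 1..K")
  if (length(msg)) msg else TRUE
})

#' RedoxMap: per-pixel optical redox ratio raster
#'
#' Pixel-wise ORR = cFAD / (NAD(P)H + cFAD), bounded in [0, 1], with a
#' validity mask: pixels whose total signal falls at or below the validity
#' floor carry no ORR value.
#'
#' @slot orr numeric matrix; NA wherever invalid.
#' @slot valid logical matrix marking pixels with a defined ORR.
#' @slot pixelSizeUm lateral pixel size (um).
#' @exportClass RedoxMap
setClass("RedoxMap",
  representation(
    orr = "matrix",
    valid = "matrix",
    pixelSizeUm = "numeric"
  )
)

setValidity("RedoxMap", function(object) {
  msg <- character()
  if (!identical(dim(object@orr), dim(object@valid)))
    msg <- c(msg, "orr and valid must share shape")
  v <- object@orr[object@valid]
  if (length(v) && (any(v < 0, na.rm = TRUE) || any(v > 1, na.rm = TRUE)))
    msg <- c(msg, "valid ORR values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' BackgroundEstimate: per-channel background level
#'
#' Median pixel intensity within the inverse object mask of a summed
#' fluorescence image (summed-image units).
#'
#' @slot value background intensity (>= 0).
#' @slot channelRole channel the estimate belongs to.
#' @slot nBackgroundPixels number of inverse-mask pixels used.
#' @exportClass BackgroundEstimate
setClass("BackgroundEstimate",
  representation(
    value = "numeric",
    channelRole = "character",
    nBackgroundPixels = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (object@value < 0) msg <- c(msg, "value must be >= 0")
    if (object@nBackgroundPixels <= 0L)
      msg <- c(msg, "nBackgroundPixels must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' CrosstalkCalibration: NAD(P)H -> FAD-band bleed-through coefficient
#'
#' Fraction of NAD(P)H emission detected in the 520 +/- 20 nm FAD band,
#' fitted as the zero-intercept regression slope of 520-band on 440-band
#' intensity across single-fluorophore standard wells. The reference
#' calibration over the physiological 0.05-0.2 mM range is 0.39.
#'
#' @slot alpha bleed-through fraction, 0 <= alpha < 1.
#' @slot fitStderr standard error of the fitted slope.
#' @slot concentrationRangeMM numeric(2), concentration range used (mM).
#' @slot nPoints number of wells entering the fit.
#' @exportClass CrosstalkCalibration
setClass("CrosstalkCalibration",
  representation(
    alpha = "numeric",
    fitStderr = "numeric",
    concentrationRangeMM = "numeric",
    nPoints = "integer"
  ),
  validity = function(object) {
    if (object@alpha < 0 || object@alpha >= 1)
      "alpha must satisfy 0 <= alpha < 1" else TRUE
  }
)

#' TileGrid: layout of mosaic tiles
#'
#' @slot rows,cols grid extent.
#' @slot placement data.frame with columns tile_id, row, col (1-based).
#' @slot tileShape integer(2): (y, x) shape shared by all tiles.
#' @exportClass TileGrid
setClass("TileGrid",
  representation(
    rows = "integer",
    cols = "integer",
    placement = "data.frame",
    tileShape = "integer"
  ),
  validity = function(object) {
    msg <- character()
    p <- object@placement
    if (!all(c("tile_id", "row", "col") %in% names(p)))
      msg <- c(msg, "placement needs columns tile_id, row, col")
    else {
      if (anyDuplicated(p[, c("row", "col")]))
        msg <- c(msg, "duplicate placement (row, col)")
      if (anyDuplicated(p$tile_id))
        msg <- c(msg, "duplicate tile_id")
      if (nrow(p) && (any(p$row < 1 | p$row > object@rows) ||
                      any(p$col < 1 | p$col > object@cols)))
        msg <- c(msg, "placement outside grid extent")
    }
    if (length(msg)) msg else TRUE
  }
)

#' GroupComparison: normality-gated multi-group test result
#'
#' Result of the two-branch comparison: if every group passes a D'Agostino-
#' Pearson normality test the parametric branch (one-way ANOVA + Bonferroni
#' post hoc) is taken, otherwise the nonparametric branch (Kruskal-Wallis +
#' Dunn's post hoc with Bonferroni adjustment).
#'
#' @slot groups named list of the input samples.
#' @slot normalityP named numeric, per-group normality p-value (NA where the
#'   group was too small to test).
#' @slot pathTaken "anova_bonferroni" or "kruskalwallis_dunn".
#' @slot omnibusP omnibus test p-value.
#' @slot pairwise data.frame with columns group1, group2, p_adjusted, stars.
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    groups = "list",
    normalityP = "numeric",
    pathTaken = "character",
    omnibusP = "numeric",
    pairwise = "data.frame"
  )
)

#' SizeOrrFit: descriptive ORR-versus-size regression
#'
#' @slot slope ORR change per um^2.
#' @slot intercept ORR at zero area.
#' @slot r Pearson correlation.
#' @slot n number of objects.
#' @exportClass SizeOrrFit
setClass("SizeOrrFit",
  representation(
    slope = "numeric",
    intercept = "numeric",
    r = "numeric",
    n = "integer"
  ),
  validity = function(object) {
    if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
      "|r| must be <= 1" else TRUE
  }
)

#' PhenotypePreset: programmed redox phenotype for the simulator
#'
#' Parameters of a synthetic spheroid cohort: the programmed median ORR, the
#' between-object spread, the rim elevation of the ORR at the object
#' periphery, the object radius range and count. Built-in presets mirror the
#' reported phenotypes of three pancreatic cancer lines (see
#' \code{\link{phenotypePreset}}).
#'
#' @slot name preset name.
#' @slot trueMedianOrr programmed population median of per-object ORR.
#' @slot orrSpread between-object standard deviation of the core ORR.
#' @slot peripheryBoost ORR added at the object rim (a band of fixed
#'   physical depth at the periphery; see \code{\link{simulateAcquisition}}).
#' @slot objectRadiusUm numeric(2): min/max object radius (um).
#' @slot nObjects objects per field.
#' @exportClass PhenotypePreset
setClass("PhenotypePreset",
  representation(
    name = "character",
    trueMedianOrr = "numeric",
    orrSpread = "numeric",
    peripheryBoost = "numeric",
    objectRadiusUm = "numeric",
    nObjects = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (object@trueMedianOrr < 0 || object@trueMedianOrr > 1)
      msg <- c(msg, "trueMedianOrr must lie in [0, 1]")
    if (length(object@objectRadiusUm) != 2L ||
        any(object@objectRadiusUm <= 0))
      msg <- c(msg, "objectRadiusUm must be a positive (min, max) pair")
    if (length(msg)) msg else TRUE
  }
)
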