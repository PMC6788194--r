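#' Estimate per-channel background from the inverse object mask
#'
#' The background level of a summed fluorescence image is the median pixel
#' intensity over the inverse mask (label 0), i.e. the inter-object space.
#' The median makes the estimate robust to stray bright pixels and, by
#' construction, invariant to whatever happens inside objects.
#'
#' @param img a \linkS4class{SummedImage} (fluorescence channel).
#' @param labels a \linkS4class{LabelMap} of matching shape.
#' @return A \linkS4class{BackgroundEstimate}.
#' @export
estimateBackground <- function(img, labels) {
  lab <- if (is(labels, "LabelMap")) labels@labels else labels
  m <- img@pixels
  if (!identical(dim(lab), dim(m))) stop("labels shape must match image")
  bgpx <- m[lab == 0L]
  if (length(bgpx) == 0L)
    stop("no background pixels: object mask covers the whole field")
  new("BackgroundEstimate", value = median(bgpx),
      channelRole = img@channelRole,
      nBackgroundPixels = length(bgpx))
}

#' Subtract a background estimate from every pixel
#'
#' Negative results are clamped to 0: negative intensities are physically
#' meaningless and would break the [0, 1] bound on the ORR.
#'
#' @param img a \linkS4class{SummedImage}.
#' @param bg a \linkS4class{BackgroundEstimate} for the same channel role,
#'   or a bare numeric background level.
#' @return A background-subtracted \linkS4class{SummedImage}.
#' @export
subtractBackground <- function(img, bg) {
  if (is(bg, "BackgroundEstimate")) {
    if (bg@channelRole != img@channelRole)
      stop(sprintf("channel role mismatch: image is '%s', background is '%s'",
                   img@channelRole, bg@channelRole))
    bgv <- bg@value
  } else bgv <- as.numeric(bg)
  out <- img
  out@pixels <- pmax(img@pixels - bgv, 0)
  out
}

#' Fit the NAD(P)H -> FAD-band bleed-through coefficient from standards
#'
#' NADH-only standard wells emit in the 440 nm band and bleed a fixed
#' fraction into the 520 nm band. The coefficient is the slope of a
#' zero-intercept least-squares regression of background-subtracted mean
#' 520-band intensity on mean 440-band intensity across wells, restricted by
#' default to the physiological 0.05-0.2 mM range over which the reference
#' calibration was derived (yielding 0.39 there). Regression through the
#' origin reflects that zero fluorophore gives zero signal after background
#' subtraction.
#'
#' If wells at concentration 0 (blanks) are present they are used to estimate
#' and subtract the per-band background, then excluded from the fit.
#'
#' @param calibSets list of wells; each well is a list with elements
#'   \code{concentrationMM}, \code{nadph} (440-band \linkS4class{SummedImage}
#'   or matrix) and \code{fad} (520-band image).
#' @param restrictRangeMM numeric(2) concentration window (mM) for the fit.
#' @param background numeric(2) per-band background levels (440, 520) on the
#'   summed scale; ignored when blanks are present.
#' @return A \linkS4class{CrosstalkCalibration}.
#' @export
estimateCrosstalk <- function(calibSets, restrictRangeMM = c(0.05, 0.2),
                              background = c(0, 0)) {
  px <- function(x) if (is(x, "SummedImage")) x@pixels else x
  conc <- vapply(calibSets, function(w) w$concentrationMM, numeric(1))
  m440 <- vapply(calibSets, function(w) mean(px(w$nadph)), numeric(1))
  m520 <- vapply(calibSets, function(w) mean(px(w$fad)), numeric(1))
  blanks <- conc == 0
  if (any(blanks))
    background <- c(mean(m440[blanks]), mean(m520[blanks]))
  keep <- !blanks & conc >= restrictRangeMM[1] & conc <= restrictRangeMM[2]
  if (sum(keep) < 3L)
    stop("need at least 3 standard wells inside the concentration range")
  x <- m440[keep] - background[1]
  y <- pmax(m520[keep] - background[2], 0)
  if (any(x <= 0))
    stop("non-positive 440-band signal after background subtraction")
  # closed-form zero-intercept least squares: slope = sum(xy) / sum(x^2)
  alpha <- sum(x * y) / sum(x^2)
  rss <- sum((y - alpha * x)^2)
  se <- sqrt(rss / (length(x) - 1) / sum(x^2))
  new("CrosstalkCalibration", alpha = alpha, fitStderr = se,
      concentrationRangeMM = as.numeric(restrictRangeMM),
      nPoints = as.integer(sum(keep)))
}

#' Correct FAD-band intensity for NAD(P)H bleed-through
#'
#' cFAD = FAD - alpha * NAD(P)H, pixel-wise, on background-subtracted summed
#' images; negative results are clamped to 0. The symmetric correction is not
#' applied: FAD emission is not detectable in the 440 nm band.
#'
#' @param fad background-subtracted 520-band \linkS4class{SummedImage}.
#' @param nadph background-subtracted 440-band image of the same shape.
#' @param alpha bleed-through fraction in [0, 1); default 0.39, the reference
#'   calibration over the physiological concentration range.
#' @return The crosstalk-corrected FAD \linkS4class{SummedImage}.
#' @export
correctFad <- function(fad, nadph, alpha = 0.39) {
  if (is(alpha, "CrosstalkCalibration")) alpha <- alpha@alpha
  if (alpha < 0 || alpha >= 1) stop("alpha must satisfy 0 <= alpha < 1")
  if (!identical(dim(fad@pixels), dim(nadph@pixels)))
    stop("fad and nadph images must share shape")
  out <- fad
  out@pixels <- pmax(fad@pixels - alpha * nadph@pixels, 0)
  out
}

#' Screen an exogenous fluorophore for interference with the redox channels
#'
#' For photosensitizer-only solutions (e.g. a benzoporphyrin-derivative
#' dilution series), reports the mean probe-induced signal in each detection
#' band as a fraction of a supplied reference signal level; the screen passes
#' iff both fractions fall below the threshold.
#'
#' @param probeSets list of wells as in \code{\link{estimateCrosstalk}}
#'   (fluorophore-only solutions; blanks at concentration 0 set background).
#' @param referenceLevels numeric(2): reference 440- and 520-band signal
#'   levels (summed scale) against which interference is expressed.
#' @param thresholdFraction maximum tolerable fraction (default 0.05).
#' @return list with elements \code{pass}, \code{fraction440},
#'   \code{fraction520}, \code{failedChannels}.
#' @export
checkInterference <- function(probeSets, referenceLevels,
                              thresholdFraction = 0.05) {
  if (missing(referenceLevels) || length(referenceLevels) != 2L)
    stop("referenceLevels (440-band, 520-band) are required")
  px <- function(x) if (is(x, "SummedImage")) x@pixels else x
  conc <- vapply(probeSets, function(w) w$concentrationMM, numeric(1))
  m440 <- vapply(probeSets, function(w) mean(px(w$nadph)), numeric(1))
  m520 <- vapply(probeSets, function(w) mean(px(w$fad)), numeric(1))
  bg <- c(0, 0)
  if (any(conc == 0))
    bg <- c(mean(m440[conc == 0]), mean(m520[conc == 0]))
  probe <- conc > 0
  f440 <- mean(pmax(m440[probe] - bg[1], 0)) / referenceLevels[1]
  f520 <- mean(pmax(m520[probe] - bg[2], 0)) / referenceLevels[2]
  failed <- c("nadph", "fad")[c(f440 >= thresholdFraction,
                                f520 >= thresholdFraction)]
  list(pass = length(failed) == 0L, fraction440 = f440, fraction520 = f520,
       failedChannels = failed)
}

#' Serialize a crosstalk calibration to JSON
#'
#' @param calib a \linkS4class{CrosstalkCalibration}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeCalibration <- function(calib, path) {
  jsonlite::write_json(list(
    alpha = calib@alpha, fit_stderr = calib@fitStderr,
    concentration_range_mM = calib@concentrationRangeMM,
    n_points = calib@nPoints,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a crosstalk calibration JSON
#'
#' @param path JSON path written by \code{\link{writeCalibration}}.
#' @return A \linkS4class{CrosstalkCalibration}.
#' @export
readCalibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CrosstalkCalibration", alpha = j$alpha, fitStderr = j$fit_stderr,
      concentrationRangeMM = as.numeric(j$concentration_range_mM),
      nPoints = as.integer(j$n_points))
}
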