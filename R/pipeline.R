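#' Run the full per-field analysis
#'
#' The complete chain for one culture field of view: sum each channel's
#' z-stack, segment spheroids/microtumors from the summed bright-field image
#' (adaptive threshold, mask cleanup, labelling), estimate per-channel
#' background as the median over the inverse mask and subtract it, correct
#' the FAD band for NAD(P)H bleed-through, compute the pixel-wise ORR map and
#' summarize every object.
#'
#' @param acq an \linkS4class{AcquisitionSet}.
#' @param windowPx,offset,polarity adaptive-threshold parameters
#'   (\code{\link{binarizeBrightfield}}).
#' @param minAreaUm2,fillHoles,keepBorderObjects mask cleanup parameters
#'   (\code{\link{cleanMask}}).
#' @param connectivity object connectivity, 4 or 8.
#' @param alpha crosstalk coefficient or a
#'   \linkS4class{CrosstalkCalibration}; default 0.39.
#' @param minSignal ORR validity floor; \code{NULL} applies the per-field
#'   default rule (\code{\link{defaultMinSignal}}).
#' @return list with elements \code{records} (per-object data.frame),
#'   \code{redox} (\linkS4class{RedoxMap}), \code{labels}
#'   (\linkS4class{LabelMap}), \code{nadph}, \code{cfad} (corrected summed
#'   images), \code{background} (per-channel estimates), \code{alpha},
#'   \code{minSignal}.
#' @export
analyzeAcquisition <- function(acq, windowPx = NULL, offset = 0.05,
                               polarity = "auto", minAreaUm2 = 500,
                               fillHoles = TRUE, keepBorderObjects = TRUE,
                               connectivity = 8L, alpha = 0.39,
                               minSignal = NULL) {
  if (is(alpha, "CrosstalkCalibration")) alpha <- alpha@alpha
  bf <- sumStack(acq@brightfield)
  nadph <- sumStack(acq@nadph)
  fad <- sumStack(acq@fad)
  ps <- bf@pixelSizeUm
  mask <- binarizeBrightfield(bf, windowPx = windowPx, offset = offset,
                              polarity = polarity)
  mask <- cleanMask(mask, pixelSizeUm = ps, minAreaUm2 = minAreaUm2,
                    fillHoles = fillHoles,
                    keepBorderObjects = keepBorderObjects)
  labels <- labelObjects(mask, connectivity = connectivity, pixelSizeUm = ps)
  bgN <- estimateBackground(nadph, labels)
  bgF <- estimateBackground(fad, labels)
  nadphC <- subtractBackground(nadph, bgN)
  fadC <- subtractBackground(fad, bgF)
  cfad <- correctFad(fadC, nadphC, alpha)
  if (is.null(minSignal))
    minSignal <- defaultMinSignal(nadphC, cfad, labels)
  redox <- computeOrrMap(nadphC, cfad, minSignal = minSignal)
  records <- summarizeObjects(redox, labels, nadphC, cfad,
                              fieldId = acq@fieldId)
  list(records = records, redox = redox, labels = labels,
       nadph = nadphC, cfad = cfad,
       background = list(nadph = bgN, fad = bgF),
       alpha = alpha, minSignal = minSignal)
}

#' Process one ex vivo slice tile into a RedoxMap
#'
#' Tissue occupies the whole tile, so no object segmentation or inverse-mask
#' background is available; the per-channel background must be supplied
#' (e.g. from an off-tissue reference tile) and defaults to 0. The tile's
#' primary readout is its median ORR over valid pixels.
#'
#' @param acq the tile's \linkS4class{AcquisitionSet}.
#' @param alpha crosstalk coefficient (default 0.39).
#' @param background numeric(2): per-channel (nadph, fad) background on the
#'   summed scale.
#' @param minSignal ORR validity floor; \code{NULL} applies the default rule
#'   over the whole tile.
#' @return list(redox = \linkS4class{RedoxMap}, medianOrr, alpha, minSignal).
#' @export
analyzeSliceTile <- function(acq, alpha = 0.39, background = c(0, 0),
                             minSignal = NULL) {
  if (is(alpha, "CrosstalkCalibration")) alpha <- alpha@alpha
  nadph <- subtractBackground(sumStack(acq@nadph), background[1])
  fad <- subtractBackground(sumStack(acq@fad), background[2])
  cfad <- correctFad(fad, nadph, alpha)
  if (is.null(minSignal)) minSignal <- defaultMinSignal(nadph, cfad)
  redox <- computeOrrMap(nadph, cfad, minSignal = minSignal)
  list(redox = redox, medianOrr = imageMedianOrr(redox),
       alpha = alpha, minSignal = minSignal)
}
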