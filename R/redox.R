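#' Compute the pixel-wise optical redox ratio map
#'
#' ORR = cFAD / (NAD(P)H + cFAD), computed pixel by pixel on the
#' background-subtracted, crosstalk-corrected summed images. The ratio is
#' contained in [0, 1] by construction (both inputs are clamped
#' non-negative). Pixels whose total signal NAD(P)H + cFAD falls at or below
#' \code{minSignal} carry no defined ratio and are marked invalid; with the
#' default floor of 0 this covers exactly the zero-denominator pixels.
#'
#' @param nadph background-subtracted 440-band \linkS4class{SummedImage}.
#' @param cfad background-subtracted, crosstalk-corrected 520-band image.
#' @param minSignal validity floor on the total signal (summed-image units,
#'   >= 0). See \code{\link{defaultMinSignal}} for the per-field rule used by
#'   the pipeline.
#' @return A \linkS4class{RedoxMap}.
#' @export
computeOrrMap <- function(nadph, cfad, minSignal = 0) {
  n <- if (is(nadph, "SummedImage")) nadph@pixels else nadph
  f <- if (is(cfad, "SummedImage")) cfad@pixels else cfad
  if (!identical(dim(n), dim(f))) stop("nadph and cfad must share shape")
  if (minSignal < 0) stop("minSignal must be >= 0")
  total <- n + f
  valid <- total > minSignal
  orr <- matrix(NA_real_, nrow(n), ncol(n))
  orr[valid] <- f[valid] / total[valid]
  ps <- if (is(nadph, "SummedImage")) nadph@pixelSizeUm else NA_real_
  new("RedoxMap", orr = orr, valid = valid, pixelSizeUm = ps)
}

#' Default validity floor for the ORR map
#'
#' The reference workflow never states a floor, but zero-denominator pixels
#' must be handled; the pipeline uses 1\% of the 99th-percentile object-pixel
#' total intensity of the field, which rejects only pixels with essentially
#' no signal. The chosen value is recorded in the run log.
#'
#' @param nadph,cfad background-subtracted (and corrected) summed images.
#' @param labels a \linkS4class{LabelMap}; the percentile is taken over
#'   object pixels when given, over all pixels otherwise.
#' @return numeric validity floor (summed-image units).
#' @export
defaultMinSignal <- function(nadph, cfad, labels = NULL) {
  n <- if (is(nadph, "SummedImage")) nadph@pixels else nadph
  f <- if (is(cfad, "SummedImage")) cfad@pixels else cfad
  total <- n + f
  if (!is.null(labels)) {
    lab <- if (is(labels, "LabelMap")) labels@labels else labels
    inobj <- total[lab > 0L]
    if (length(inobj)) total <- inobj
  }
  0.01 * unname(quantile(total, 0.99))
}

#' Per-object redox statistics
#'
#' One record per labelled object. The primary statistic is the median of
#' pixel ORRs over the object's valid pixels; the mean of pixel ORRs and the
#' overall ORR — the ratio of object-mean intensities,
#' mean(cFAD) / (mean(NAD(P)H) + mean(cFAD)) — are reported alongside because
#' the two averaging orders genuinely differ. Objects with no valid pixels
#' carry NA ORR statistics.
#'
#' @param redox a \linkS4class{RedoxMap}.
#' @param labels a \linkS4class{LabelMap} of matching shape.
#' @param nadph,cfad the background-subtracted (and corrected) summed images.
#' @param fieldId field identifier recorded in each row.
#' @return data.frame with columns field_id, object_id, area_um2, median_orr,
#'   mean_orr, overall_orr, mean_nadph, mean_cfad, touches_border,
#'   n_valid_pixels.
#' @export
summarizeObjects <- function(redox, labels, nadph, cfad, fieldId = "field") {
  lab <- if (is(labels, "LabelMap")) labels@labels else labels
  K <- max(lab)
  n <- if (is(nadph, "SummedImage")) nadph@pixels else nadph
  f <- if (is(cfad, "SummedImage")) cfad@pixels else cfad
  stopifnot(identical(dim(lab), dim(redox@orr)),
            identical(dim(lab), dim(n)), identical(dim(lab), dim(f)))
  ps <- if (is(labels, "LabelMap")) labels@pixelSizeUm else redox@pixelSizeUm
  borderIds <- .touchesBorder(lab)
  rows <- lapply(seq_len(K), function(k) {
    sel <- lab == k
    ok <- sel & redox@valid
    ov <- redox@orr[ok]
    mn <- mean(n[sel]); mf <- mean(f[sel])
    data.frame(
      field_id = fieldId,
      object_id = k,
      area_um2 = sum(sel) * ps^2,
      median_orr = if (length(ov)) median(ov) else NA_real_,
      mean_orr = if (length(ov)) mean(ov) else NA_real_,
      overall_orr = if (mn + mf > 0) mf / (mn + mf) else NA_real_,
      mean_nadph = mn,
      mean_cfad = mf,
      touches_border = k %in% borderIds,
      n_valid_pixels = sum(ok),
      stringsAsFactors = FALSE
    )
  })
  if (K == 0L)
    return(as.data.frame(setNames(
      lapply(.OBJECT_TABLE_COLUMNS, function(x) logical(0)),
      .OBJECT_TABLE_COLUMNS)))
  do.call(rbind, rows)
}

#' Median ORR of an image or mosaic
#'
#' The per-image median ORR over valid pixels — the primary readout for ex
#' vivo tissue slices, where tissue occupies the tile and no per-object
#' restriction applies. For culture fields, set \code{restrictToObjects} to
#' pool only object pixels.
#'
#' @param redox a \linkS4class{RedoxMap}.
#' @param restrictToObjects restrict to pixels inside labelled objects.
#' @param labels a \linkS4class{LabelMap}; required when restricting.
#' @return median ORR (fraction).
#' @export
imageMedianOrr <- function(redox, restrictToObjects = FALSE, labels = NULL) {
  sel <- redox@valid
  if (restrictToObjects) {
    if (is.null(labels)) stop("labels required when restrictToObjects = TRUE")
    lab <- if (is(labels, "LabelMap")) labels@labels else labels
    sel <- sel & lab > 0L
  }
  v <- redox@orr[sel]
  if (!length(v)) stop("no valid pixels in scope")
  median(v)
}
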