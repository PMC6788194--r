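#' Construct a ChannelStack from an array
#'
#' @param pixels 3D array (z, y, x) or a 2D matrix (treated as a single plane).
#' @param channelRole one of \code{"brightfield"}, \code{"nadph"},
#'   \code{"fad"}, \code{"other"}.
#' @param pixelSizeUm lateral pixel size (um).
#' @param zStepUm z spacing (um); the reference protocol uses 0.1 um.
#' @param bitDepth source bit depth.
#' @return A \linkS4class{ChannelStack}.
#' @export
ChannelStack <- function(pixels, channelRole = c("other", "brightfield",
                                                 "nadph", "fad"),
                         pixelSizeUm = NA_real_, zStepUm = 0.1,
                         bitDepth = 16L) {
  channelRole <- match.arg(channelRole)
  if (is.matrix(pixels))
    pixels <- array(pixels, dim = c(1L, dim(pixels)))
  new("ChannelStack", pixels = pixels, channelRole = channelRole,
      zStepUm = zStepUm, pixelSizeUm = as.numeric(pixelSizeUm),
      bitDepth = as.integer(bitDepth))
}

#' Construct an AcquisitionSet
#'
#' @param brightfield,nadph,fad \linkS4class{ChannelStack} objects.
#' @param fieldId field identifier.
#' @param fovUm field-of-view width (um); if given and the stacks carry no
#'   pixel size, the pixel size is derived as \code{fovUm / width}.
#' @return An \linkS4class{AcquisitionSet}.
#' @export
AcquisitionSet <- function(brightfield, nadph, fad, fieldId = "field",
                           fovUm = NA_real_) {
  if (!is.na(fovUm)) {
    width <- dim(brightfield@pixels)[3]
    ps <- fovUm / width
    for (nm in c("brightfield", "nadph", "fad")) {
      cs <- get(nm)
      if (is.na(cs@pixelSizeUm)) {
        cs@pixelSizeUm <- ps
        assign(nm, cs)
      }
    }
  }
  new("AcquisitionSet", brightfield = brightfield, nadph = nadph, fad = fad,
      fieldId = as.character(fieldId), fovUm = as.numeric(fovUm))
}

# pixel size (um) from embedded TIFF resolution tags, NA if absent/unusable
.pixelSizeFromTiffInfo <- function(page) {
  xres <- attr(page, "x.resolution")
  unit <- attr(page, "resolution.unit")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NA_real_)
  if (is.null(unit)) return(NA_real_)
  per_um <- switch(as.character(unit),
                   "inch" = xres / 25400, "cm" = xres / 1e4, NULL)
  if (is.null(per_um) || per_um <= 0) return(NA_real_)
  1 / per_um
}

#' Read a multi-page grayscale TIFF into a ChannelStack
#'
#' Planes are returned in file page order. The pixel size is resolved with
#' the priority: explicit \code{pixelSizeUm} argument, embedded TIFF
#' resolution tags, then \code{fovUm / width}.
#'
#' @param path a single- or multi-page grayscale TIFF / OME-TIFF.
#' @param channelRole channel role to record.
#' @param pixelSizeUm explicit pixel size (um), overrides everything.
#' @param fovUm field-of-view width (um), used when no other source exists.
#' @param zStepUm z spacing (um).
#' @return A \linkS4class{ChannelStack}; RGB/multi-sample pages or mismatched
#'   plane shapes raise an error naming the offending page.
#' @export
readStack <- function(path, channelRole = "other", pixelSizeUm = NA_real_,
                      fovUm = NA_real_, zStepUm = 0.1) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- NULL
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) != 2L)
      stop(sprintf("page %d of '%s' is not single-sample grayscale", i, path))
    if (is.null(shp)) shp <- dim(p)
    else if (!identical(dim(p), shp))
      stop(sprintf("page %d of '%s' has shape %dx%d, expected %dx%d",
                   i, path, dim(p)[1], dim(p)[2], shp[1], shp[2]))
  }
  arr <- array(0, dim = c(length(pages), shp))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  if (is.na(pixelSizeUm)) pixelSizeUm <- .pixelSizeFromTiffInfo(pages[[1]])
  if (is.na(pixelSizeUm) && !is.na(fovUm)) pixelSizeUm <- fovUm / shp[2]
  ChannelStack(arr, channelRole = channelRole, pixelSizeUm = pixelSizeUm,
               zStepUm = zStepUm, bitDepth = as.integer(bits))
}

#' Write a ChannelStack as a multi-page grayscale TIFF
#'
#' Integer intensities are written losslessly at the stack's bit depth, so a
#' write/read round trip reproduces pixel values exactly.
#'
#' @param stack a \linkS4class{ChannelStack} with integer-valued intensities.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  bits <- if (stack@bitDepth > 8L) 16L else 8L
  maxv <- 2^bits - 1
  px <- stack@pixels
  if (any(px > maxv))
    stop("intensities exceed the representable range at bit depth ", bits)
  planes <- lapply(seq_len(dim(px)[1]), function(i) px[i, , ] / maxv)
  tiff::writeTIFF(planes, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

.OBJECT_TABLE_COLUMNS <- c("field_id", "object_id", "area_um2", "median_orr",
                           "mean_orr", "overall_orr", "mean_nadph",
                           "mean_cfad", "touches_border", "n_valid_pixels")

#' Write per-object redox records to CSV
#'
#' Columns are written in a stable, documented order: field_id, object_id,
#' area_um2, median_orr, mean_orr, overall_orr, mean_nadph, mean_cfad,
#' touches_border, n_valid_pixels. Undefined statistics (objects without
#' valid ORR pixels) become empty cells.
#'
#' @param records data.frame of object records (see
#'   \code{\link{summarizeObjects}}); may have zero rows.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeObjectTable <- function(records, path) {
  cols <- .OBJECT_TABLE_COLUMNS
  if (nrow(records) == 0L && !all(cols %in% names(records)))
    records <- as.data.frame(setNames(
      lapply(cols, function(x) logical(0)), cols))
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("records lack columns: ", paste(missing, collapse = ", "))
  out <- records[, cols, drop = FALSE]
  for (nm in cols) out[[nm]][is.nan(out[[nm]])] <- NA
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-object CSV written by writeObjectTable
#'
#' @param path CSV path.
#' @return data.frame with empty cells restored as NA.
#' @export
readObjectTable <- function(path) {
  read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}

# 256-step perceptually ordered ramp, fixed so heatmaps compare across fields
.heatmapPalette <- function() grDevices::hcl.colors(256L, "viridis")
.INVALID_COLOR <- c(0.5, 0.5, 0.5)   # reserved mid-grey for invalid pixels

#' Render a RedoxMap as a heatmap PNG
#'
#' Uses a fixed colour scale over [0, 1] (never per-image autoscaled) so
#' heatmaps are comparable across fields; invalid pixels are rendered in a
#' reserved mid-grey.
#'
#' @param redox a \linkS4class{RedoxMap}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeHeatmap <- function(redox, path) {
  pal <- .heatmapPalette()
  rgbpal <- grDevices::col2rgb(pal) / 255
  o <- redox@orr
  idx <- pmin(pmax(as.integer(round(o * 255)) + 1L, 1L), 256L)
  h <- nrow(o); w <- ncol(o)
  img <- array(0, dim = c(h, w, 3))
  ok <- redox@valid & !is.na(idx)
  for (k in 1:3) {
    ch <- matrix(.INVALID_COLOR[k], h, w)
    ch[ok] <- rgbpal[k, idx[ok]]
    img[, , k] <- ch
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Map ORR values to heatmap palette indices
#'
#' The palette lookup used by \code{\link{writeHeatmap}}: a monotone map from
#' ORR in [0, 1] to 256 colour-ramp indices. Exposed for testing and for
#' building colour bars.
#'
#' @param orr numeric vector of ORR values in [0, 1].
#' @return integer palette indices in 1..256.
#' @export
heatmapIndex <- function(orr) {
  pmin(pmax(as.integer(round(orr * 255)) + 1L, 1L), 256L)
}
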