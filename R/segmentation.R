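#' @importFrom EBImage filter2 fillHull bwlabel
NULL

# Gaussian-weighted local mean with replicate padding (no FFT wrap-around).
# sigma is tied to the window so the kernel support matches window_px.
.localMeanGaussian <- function(m, windowPx) {
  half <- windowPx %/% 2L
  sigma <- windowPx / 6
  g <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, half), seq_len(nr), rep(nr, half))
  ci <- c(rep(1L, half), seq_len(nc), rep(nc, half))
  padded <- m[ri, ci]
  sm <- EBImage::filter2(padded, kern, boundary = "replicate")
  sm[half + seq_len(nr), half + seq_len(nc)]
}

#' Adaptive-threshold binarization of a summed bright-field image
#'
#' Each pixel is compared with a Gaussian-weighted local mean of its
#' neighbourhood, which makes the binarization invariant to smooth
#' inhomogeneous illumination: a pixel is foreground iff it deviates from the
#' local mean, in the chosen polarity direction, by more than
#' \code{offset} times the local mean.
#'
#' @param img a \linkS4class{SummedImage} (bright-field).
#' @param windowPx odd neighbourhood width in pixels, >= 3 and smaller than
#'   the image; default is image width / 8 rounded to odd.
#' @param offset relative deviation from the local mean required to call a
#'   pixel foreground (default 0.05).
#' @param polarity \code{"objects_darker"}, \code{"objects_brighter"} or
#'   \code{"auto"}. Bright-field object contrast depends on focus, so
#'   \code{"auto"} picks the polarity whose candidate mask separates
#'   foreground from background intensity the most (largest relative
#'   difference of foreground and background means). A foreground-fraction
#'   rule is fragile here: adaptive thresholding leaves a faint
#'   opposite-polarity halo around every strong object whose area can rival
#'   the objects themselves.
#' @return logical matrix, TRUE = foreground.
#' @export
binarizeBrightfield <- function(img, windowPx = NULL, offset = 0.05,
                                polarity = c("auto", "objects_darker",
                                             "objects_brighter")) {
  polarity <- match.arg(polarity)
  m <- if (is(img, "SummedImage")) img@pixels else img
  if (is.null(windowPx)) {
    windowPx <- as.integer(round(ncol(m) / 8))
    if (windowPx %% 2L == 0L) windowPx <- windowPx + 1L
    windowPx <- max(windowPx, 3L)
  }
  if (windowPx %% 2L != 1L) stop("windowPx must be odd")
  if (windowPx < 3L) stop("windowPx must be >= 3")
  if (windowPx >= min(dim(m))) stop("windowPx must be smaller than the image")
  loc <- .localMeanGaussian(m, windowPx)
  darker <- m < (1 - offset) * loc
  if (polarity == "objects_darker") return(darker)
  brighter <- m > (1 + offset) * loc
  if (polarity == "objects_brighter") return(brighter)
  contrast <- function(fg) {
    if (!any(fg) || all(fg)) return(0)
    abs(mean(m[fg]) - mean(m[!fg])) / mean(m)
  }
  if (contrast(brighter) > contrast(darker)) brighter else darker
}

# connected components; EBImage::bwlabel is 4-connected, 8-connectivity is
# obtained by merging diagonally adjacent labels (union-find over labels)
.labelCC <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  K <- max(lab)
  if (connectivity == 8L && K > 1L) {
    parent <- seq_len(K)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    unite <- function(a, b) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
    nr <- nrow(lab); nc <- ncol(lab)
    diagPairs <- function(a, b) {
      sel <- a > 0L & b > 0L & a != b
      unique(cbind(a[sel], b[sel]))
    }
    p1 <- diagPairs(lab[-nr, -nc], lab[-1, -1])
    p2 <- diagPairs(lab[-nr, -1], lab[-1, -nc])
    for (p in list(p1, p2)) if (nrow(p))
      for (i in seq_len(nrow(p))) unite(p[i, 1], p[i, 2])
    root <- vapply(seq_len(K), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  # relabel 1..K in raster-scan (row-major) order of first-encountered pixel
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    nr <- nrow(lab)
    firstIdx <- vapply(ids, function(id) {
      w <- which(lab == id)
      r <- (w - 1L) %% nr + 1L
      cc <- (w - 1L) %/% nr + 1L
      min((r - 1L) * ncol(lab) + cc)
    }, numeric(1))
    ord <- ids[order(firstIdx)]
    remap <- integer(max(ids))
    remap[ord] <- seq_along(ord)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

.touchesBorder <- function(lab) {
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border[border > 0L]
}

#' Clean a binary object mask
#'
#' Fills holes, removes components smaller than a physical area floor, and
#' optionally drops components touching the image border. Border objects are
#' kept by default (ex vivo mosaics clip many objects) and flagged
#' \code{touches_border} downstream.
#'
#' @param mask logical matrix.
#' @param pixelSizeUm lateral pixel size (um), used to convert the area floor.
#' @param minAreaUm2 minimum object area in um^2 (default 500, well below the
#'   smallest reported microtumors of ~3.3e4 um^2).
#' @param fillHoles fill enclosed holes in each component.
#' @param keepBorderObjects keep components touching the image border.
#' @return logical matrix.
#' @export
cleanMask <- function(mask, pixelSizeUm, minAreaUm2 = 500,
                      fillHoles = TRUE, keepBorderObjects = TRUE) {
  m <- mask
  storage.mode(m) <- "integer"
  if (fillHoles) {
    m <- matrix(as.integer(round(EBImage::fillHull(m))), nrow(m), ncol(m))
  }
  lab <- .labelCC(m > 0L, 8L)
  if (max(lab) == 0L) return(lab > 0L)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  minPx <- minAreaUm2 / pixelSizeUm^2
  drop <- which(areas < minPx)
  if (!keepBorderObjects) drop <- union(drop, .touchesBorder(lab))
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab > 0L
}

#' Label connected objects
#'
#' Connected components of the mask are labelled 1..K in deterministic
#' raster-scan order of the first-encountered pixel (row-major, origin
#' top-left), so repeated runs yield identical label maps.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param pixelSizeUm lateral pixel size (um) carried into the result.
#' @return A \linkS4class{LabelMap}.
#' @export
labelObjects <- function(mask, connectivity = 8L, pixelSizeUm = NA_real_) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- .labelCC(mask, connectivity)
  new("LabelMap", labels = lab, nObjects = as.integer(max(lab)),
      pixelSizeUm = as.numeric(pixelSizeUm))
}
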