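#' Collapse a z-stack into one high-SNR image by summation
#'
#' The repeated scans of the shallow z-stack (30 planes at 0.1 um for
#' cultures, 15 for ex vivo slices) are summed pixel-wise into a wide
#' accumulator. Summation, not averaging, is used; the ORR is a ratio so the
#' distinction cancels there, but absolute background levels scale with the
#' number of planes, which is therefore carried in the result.
#'
#' @param stack a \linkS4class{ChannelStack} with at least one plane.
#' @return A \linkS4class{SummedImage}; no saturation or clipping occurs.
#' @examples
#' cs <- ChannelStack(array(10, dim = c(30, 4, 4)), "nadph", pixelSizeUm = 1)
#' max(pixels(sumStack(cs)))  # 300
#' @export
sumStack <- function(stack) {
  stopifnot(is(stack, "ChannelStack"))
  d <- dim(stack@pixels)
  if (d[1] < 1L) stop("stack has no planes")
  s <- apply(stack@pixels, c(2, 3), sum)
  new("SummedImage", pixels = s, channelRole = stack@channelRole,
      pixelSizeUm = stack@pixelSizeUm, nPlanesSummed = as.integer(d[1]))
}

# internal: wrap a plain matrix as a SummedImage with given metadata
.asSummed <- function(m, role, pixelSizeUm, nPlanes = 1L) {
  new("SummedImage", pixels = m, channelRole = role,
      pixelSizeUm = pixelSizeUm, nPlanesSummed = as.integer(nPlanes))
}
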