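#' Construct a TileGrid
#'
#' @param placement data.frame with columns tile_id, row, col (1-based grid
#'   coordinates).
#' @param tileShape integer(2): (y, x) pixel shape shared by all tiles.
#' @param rows,cols grid extent; default is the maximum placed coordinate.
#' @return A \linkS4class{TileGrid}.
#' @export
TileGrid <- function(placement, tileShape, rows = max(placement$row),
                     cols = max(placement$col)) {
  placement$tile_id <- as.character(placement$tile_id)
  new("TileGrid", rows = as.integer(rows), cols = as.integer(cols),
      placement = placement, tileShape = as.integer(tileShape))
}

#' Read a tile layout file
#'
#' Plain CSV with columns tile_id, row, col; alternatively tile ids following
#' the \code{row_col} filename convention (e.g. \code{"2_3"}) can be expanded
#' with \code{layoutFromIds}.
#'
#' @param path CSV path.
#' @param tileShape integer(2) tile pixel shape.
#' @return A \linkS4class{TileGrid}.
#' @export
readTileLayout <- function(path, tileShape) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  TileGrid(p, tileShape)
}

#' Build a layout from row_col tile ids
#'
#' @param tileIds character vector like \code{c("1_1", "1_2", "2_1")}.
#' @param tileShape integer(2) tile pixel shape.
#' @return A \linkS4class{TileGrid}.
#' @export
layoutFromIds <- function(tileIds, tileShape) {
  parts <- strsplit(tileIds, "_", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (!all(ok)) stop("tile ids must follow the row_col convention: ",
                     paste(tileIds[!ok], collapse = ", "))
  TileGrid(data.frame(
    tile_id = tileIds,
    row = as.integer(vapply(parts, `[`, "", 1)),
    col = as.integer(vapply(parts, `[`, "", 2)),
    stringsAsFactors = FALSE
  ), tileShape)
}

#' Stitch per-tile ORR heatmaps into a slice mosaic
#'
#' Abutting (non-overlapping) placement of tiles into a
#' rows*tile_y by cols*tile_x mosaic — no blending, registration or
#' interpolation: every mosaic pixel equals the corresponding source-tile
#' pixel. Grid cells without a placed tile become invalid pixels.
#'
#' @param tiles named list mapping tile_id to \linkS4class{RedoxMap}.
#' @param grid a \linkS4class{TileGrid}.
#' @return The mosaic \linkS4class{RedoxMap}.
#' @export
stitchTiles <- function(tiles, grid) {
  p <- grid@placement
  missing <- setdiff(p$tile_id, names(tiles))
  if (length(missing))
    stop("no tile supplied for placement(s): ", paste(missing, collapse = ", "))
  ty <- grid@tileShape[1]; tx <- grid@tileShape[2]
  H <- grid@rows * ty; W <- grid@cols * tx
  orr <- matrix(NA_real_, H, W)
  valid <- matrix(FALSE, H, W)
  ps <- NA_real_
  for (i in seq_len(nrow(p))) {
    t <- tiles[[p$tile_id[i]]]
    if (!identical(dim(t@orr), as.integer(c(ty, tx))))
      stop(sprintf("tile '%s' has shape %dx%d, grid expects %dx%d",
                   p$tile_id[i], nrow(t@orr), ncol(t@orr), ty, tx))
    rr <- (p$row[i] - 1L) * ty + seq_len(ty)
    cc <- (p$col[i] - 1L) * tx + seq_len(tx)
    orr[rr, cc] <- t@orr
    valid[rr, cc] <- t@valid
    if (is.na(ps)) ps <- t@pixelSizeUm
  }
  new("RedoxMap", orr = orr, valid = valid, pixelSizeUm = ps)
}
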