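# Naive brute-force reference implementations, independent of the package's
# vectorized code paths; used as oracles on small rasters.

# pixel-by-pixel ORR with explicit double loop
refOrrMap <- function(nadph, cfad, minSignal = 0) {
  nr <- nrow(nadph); nc <- ncol(nadph)
  orr <- matrix(NA_real_, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    tot <- nadph[i, j] + cfad[i, j]
    if (tot > minSignal) {
      valid[i, j] <- TRUE
      orr[i, j] <- cfad[i, j] / tot
    }
  }
  list(orr = orr, valid = valid)
}

# connected-component labelling by breadth-first flood fill, raster-scan
# (row-major) seeding order
refLabel <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    moves <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    moves <- rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  k <- 0L
  qy <- integer(nr * nc); qx <- integer(nr * nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      head <- 1L; tail <- 1L
      qy[1] <- i; qx[1] <- j
      lab[i, j] <- k
      while (head <= tail) {
        py <- qy[head]; px <- qx[head]; head <- head + 1L
        for (m in seq_len(nrow(moves))) {
          y <- py + moves[m, 1]; x <- px + moves[m, 2]
          if (y >= 1 && y <= nr && x >= 1 && x <= nc &&
              mask[y, x] && lab[y, x] == 0L) {
            lab[y, x] <- k
            tail <- tail + 1L
            qy[tail] <- y; qx[tail] <- x
          }
        }
      }
    }
  }
  lab
}

# background as an explicit loop over label-0 pixels
refBackground <- function(img, lab) {
  vals <- c()
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    if (lab[i, j] == 0L) vals <- c(vals, img[i, j])
  median(vals)
}

# build a SummedImage fixture from a matrix
summed <- function(m, role = "nadph", ps = 1, n = 1L) {
  new("SummedImage", pixels = m, channelRole = role,
      pixelSizeUm = ps, nPlanesSummed = as.integer(n))
}

# an anti-aliased dark disk on a bright background, with known ground truth
diskImage <- function(ny = 128, nx = 128, cy = 64, cx = 64, r = 30,
                      bg = 1000, fg = 100) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  d <- sqrt((yy - cy)^2 + (xx - cx)^2)
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  list(img = bg - (bg - fg) * cov, truthMask = d <= r)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
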