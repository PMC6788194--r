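#' Built-in phenotype presets
#'
#' Presets mirror the reported spheroid redox phenotypes of three pancreatic
#' ductal adenocarcinoma lines: AsPC-1-like (median ORR 0.21, spread 0.06),
#' PANC-1-like (0.12, spread 0.12) and MIA PaCa-2-like (0.05, spread 0.02).
#' All presets add a small rim elevation of the ORR (the periphery of
#' spheroids reads more oxidized than the core), which is what makes
#' size-versus-ORR trend tests possible on synthetic cohorts.
#'
#' @param name one of \code{"AsPC-1-like"}, \code{"PANC-1-like"},
#'   \code{"MIA PaCa-2-like"}.
#' @return A \linkS4class{PhenotypePreset}.
#' @export
phenotypePreset <- function(name = c("AsPC-1-like", "PANC-1-like",
                                     "MIA PaCa-2-like")) {
  name <- match.arg(name)
  p <- switch(name,
    "AsPC-1-like" = list(orr = 0.21, spread = 0.06),
    "PANC-1-like" = list(orr = 0.12, spread = 0.12),
    "MIA PaCa-2-like" = list(orr = 0.05, spread = 0.02))
  new("PhenotypePreset", name = name, trueMedianOrr = p$orr,
      orrSpread = p$spread, peripheryBoost = 0.05,
      objectRadiusUm = c(50, 110), nObjects = 8L)
}

# stratified normal draws: cohort quantiles are realized accurately so the
# programmed population median is met in every simulated cohort, while
# object-to-object spread stays at the programmed level
.stratifiedNormal <- function(n, mean, sd) {
  u <- (seq_len(n) - 0.5 + runif(n, -0.4, 0.4)) / n
  sample(stats::qnorm(u, mean, sd))
}

# per-plane noise: Poisson shot noise on expected counts + Gaussian read
# noise, quantized to the 16-bit detector range; with noise fully off the
# exact expected values are returned un-quantized
.noisyPlanes <- function(expected, nPlanes, noise) {
  poisson <- isTRUE(noise$poisson)
  readSigma <- if (is.null(noise$readSigma)) 0 else noise$readSigma
  d <- dim(expected)
  out <- array(0, dim = c(nPlanes, d))
  for (z in seq_len(nPlanes)) {
    if (poisson) plane <- rpois(length(expected), lambda = expected)
    else plane <- as.numeric(expected)
    if (readSigma > 0) plane <- plane + rnorm(length(plane), 0, readSigma)
    if (poisson || readSigma > 0)
      plane <- pmin(pmax(round(plane), 0), 65535)
    out[z, , ] <- plane
  }
  out
}

#' Simulate one acquisition field with full ground truth
#'
#' Renders anti-aliased disk-shaped spheroids on a darker-object bright-field
#' background and splits a programmed total fluorescence intensity between
#' the two redox channels so that cFAD / (NAD(P)H + cFAD) equals the
#' programmed per-pixel ORR before background, crosstalk and noise are
#' layered on. Per-object core ORRs follow the preset; a rim of fixed
#' physical depth (\code{rimWidthUm}) is elevated by the preset's periphery
#' boost. A fixed rim depth mimics the characteristic scale of oxygen and
#' nutrient gradients, so smaller objects carry a proportionally larger
#' oxidized rim and cohorts with varying radii show a negative size-ORR
#' trend; at the preset radii (>= 50 um) the rim stays a minority of the
#' area, leaving per-object median ORRs at the programmed core values.
#' Background
#' offsets are programmed on the summed scale, crosstalk is injected into
#' the FAD band at the given coefficient, and Poisson + Gaussian read noise
#' act per plane before summation. Every stochastic draw is governed by
#' \code{seed}, so outputs are bit-identical across runs.
#'
#' @param preset a \linkS4class{PhenotypePreset} (or preset name).
#' @param imageShape integer(2) raster shape (y, x); default 256 x 256.
#' @param fovUm field-of-view width (um); default 1272.32, the reference
#'   system's field, giving the pixel size as \code{fovUm / x}.
#' @param nPlanes z planes per channel (default 30; ex vivo slices use 15).
#' @param background numeric(2): per-channel additive background for
#'   (nadph, fad), on the summed scale.
#' @param alpha injected NAD(P)H -> FAD-band crosstalk coefficient.
#' @param noise list(poisson = flag, readSigma = per-plane Gaussian sd).
#' @param seed integer seed.
#' @param fieldId field identifier.
#' @param rimWidthUm physical depth of the ORR-elevated rim (um).
#' @param objectIntensityPerPlane expected total fluorescence counts per
#'   plane inside an object.
#' @param brightfieldLevelPerPlane bright-field background counts per plane.
#' @param brightfieldContrast fractional darkening of objects in
#'   bright-field.
#' @return list with elements \code{acquisition} (an
#'   \linkS4class{AcquisitionSet}) and \code{truth} (per-pixel true ORR
#'   raster, true label matrix, per-object table, programmed background,
#'   alpha, noise parameters and seed).
#' @export
simulateAcquisition <- function(preset, imageShape = c(256L, 256L),
                                fovUm = 1272.32, nPlanes = 30L,
                                background = c(nadph = 50, fad = 50),
                                alpha = 0.39,
                                noise = list(poisson = TRUE, readSigma = 2),
                                seed = 1L, fieldId = "field1",
                                rimWidthUm = 12,
                                objectIntensityPerPlane = 600,
                                brightfieldLevelPerPlane = 800,
                                brightfieldContrast = 0.4) {
  if (is.character(preset)) preset <- phenotypePreset(preset)
  set.seed(seed)
  ny <- imageShape[1]; nx <- imageShape[2]
  ps <- fovUm / nx
  rminPx <- preset@objectRadiusUm[1] / ps
  rmaxPx <- preset@objectRadiusUm[2] / ps
  if (2 * rmaxPx + 4 > min(ny, nx))
    stop("objects do not fit in the frame at this pixel size")
  K <- preset@nObjects
  centers <- matrix(0, 0, 2); radii <- numeric(0)
  tries <- 0L
  while (length(radii) < K && tries < 5000L) {
    tries <- tries + 1L
    r <- runif(1, rminPx, rmaxPx)
    cy <- runif(1, r + 2, ny - r - 1)
    cx <- runif(1, r + 2, nx - r - 1)
    if (nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
            radii + r + 10)) {
      centers <- rbind(centers, c(cy, cx)); radii <- c(radii, r)
    }
  }
  if (length(radii) < K)
    stop("could not place ", K, " non-overlapping objects in the frame")
  coreOrr <- pmin(pmax(.stratifiedNormal(K, preset@trueMedianOrr,
                                         preset@orrSpread), 0), 1)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  coverage <- matrix(0, ny, nx)
  trueOrr <- matrix(NA_real_, ny, nx)
  trueLab <- matrix(0L, ny, nx)
  objMedian <- numeric(K)
  for (k in seq_len(K)) {
    d <- sqrt((yy - centers[k, 1])^2 + (xx - centers[k, 2])^2)
    cov_k <- pmin(pmax(radii[k] + 0.5 - d, 0), 1)  # 1-px anti-aliased edge
    rimPx <- rimWidthUm / ps
    w <- pmin(pmax((d - (radii[k] - rimPx)) / rimPx, 0), 1)
    t_k <- pmin(pmax(coreOrr[k] + preset@peripheryBoost * w, 0), 1)
    sel <- cov_k > 0
    coverage[sel] <- cov_k[sel]
    trueOrr[sel] <- t_k[sel]
    inobj <- cov_k >= 0.5
    trueLab[inobj] <- k
    objMedian[k] <- median(t_k[inobj])
  }
  # relabel truth objects in raster-scan order of first-encountered pixel,
  # the same deterministic convention labelObjects uses, so object k in the
  # truth table pairs with object k in the pipeline output
  firstIdx <- vapply(seq_len(K), function(k) {
    w <- which(trueLab == k)
    r <- (w - 1L) %% ny + 1L
    cc <- (w - 1L) %/% ny + 1L
    min((r - 1L) * nx + cc)
  }, numeric(1))
  ord <- order(firstIdx)
  remap <- integer(K); remap[ord] <- seq_len(K)
  trueLab[trueLab > 0L] <- remap[trueLab[trueLab > 0L]]
  centers <- centers[ord, , drop = FALSE]
  radii <- radii[ord]
  coreOrr <- coreOrr[ord]
  objMedian <- objMedian[ord]
  t <- ifelse(is.na(trueOrr), 0, trueOrr)
  itot <- objectIntensityPerPlane * coverage
  nadphTrue <- (1 - t) * itot
  fadTrue <- t * itot
  nadphExp <- nadphTrue + background[1] / nPlanes
  fadExp <- fadTrue + alpha * nadphTrue + background[2] / nPlanes
  bfExp <- brightfieldLevelPerPlane * (1 - brightfieldContrast * coverage)
  mk <- function(expected, role) {
    ChannelStack(.noisyPlanes(expected, nPlanes, noise), role,
                 pixelSizeUm = ps)
  }
  acq <- AcquisitionSet(
    brightfield = mk(bfExp, "brightfield"),
    nadph = mk(nadphExp, "nadph"),
    fad = mk(fadExp, "fad"),
    fieldId = fieldId, fovUm = fovUm)
  truth <- list(
    trueOrr = trueOrr,
    trueLabels = trueLab,
    objects = data.frame(
      object_id = seq_len(K),
      center_y = centers[, 1], center_x = centers[, 2],
      radius_um = radii * ps,
      core_orr = coreOrr,
      true_median_orr = objMedian
    ),
    background = unname(background), alpha = alpha,
    noise = noise, seed = seed, pixelSizeUm = ps, nPlanes = nPlanes
  )
  list(acquisition = acq, truth = truth)
}

#' Simulate a fluorophore standard-curve image set
#'
#' Emulates imaging a dilution series of single-fluorophore wells. NADH
#' wells emit in the 440 nm band proportionally to concentration, with an
#' \code{alpha} fraction bleeding into the 520 nm band; FAD wells emit only
#' in the 520 nm band (FAD emission is not detectable at 440 +/- 20 nm);
#' probe wells (exogenous photosensitizer) emit in neither band by default.
#' Blank wells at concentration 0 are prepended for background estimation.
#'
#' @param fluorophore \code{"nadh"}, \code{"fad"} or \code{"probe"}.
#' @param concentrationsMM positive concentrations (mM).
#' @param alpha NADH bleed-through coefficient into the 520 nm band.
#' @param nReplicates wells per concentration.
#' @param noise list(poisson, readSigma) as in
#'   \code{\link{simulateAcquisition}}.
#' @param seed integer seed.
#' @param shape well image shape.
#' @param nPlanes planes per stack.
#' @param background numeric(2) per-band background, summed scale.
#' @param countsPerMMPerPlane emission counts per plane per mM in the
#'   fluorophore's own band.
#' @param probeLeak numeric(2): probe emission per plane per mM in the
#'   (440, 520) bands, for interference experiments.
#' @return list of wells; each well is
#'   list(concentrationMM, replicate, nadph, fad) with
#'   \linkS4class{SummedImage} members. The injected parameters are attached
#'   as the \code{"truth"} attribute.
#' @export
simulateStandardCurve <- function(fluorophore = c("nadh", "fad", "probe"),
                                  concentrationsMM,
                                  alpha = 0.39, nReplicates = 1L,
                                  noise = list(poisson = TRUE, readSigma = 2),
                                  seed = 1L, shape = c(64L, 64L),
                                  nPlanes = 30L, background = c(50, 50),
                                  countsPerMMPerPlane = 4000,
                                  probeLeak = c(0, 0)) {
  fluorophore <- match.arg(fluorophore)
  if (any(concentrationsMM <= 0)) stop("concentrations must be positive")
  set.seed(seed)
  conc <- c(rep(0, nReplicates), rep(concentrationsMM, each = nReplicates))
  wells <- vector("list", length(conc))
  for (i in seq_along(conc)) {
    c_i <- conc[i]
    sig <- countsPerMMPerPlane * c_i
    e440 <- switch(fluorophore, nadh = sig, fad = 0, probe = probeLeak[1] * c_i)
    e520 <- switch(fluorophore, nadh = alpha * sig, fad = sig,
                   probe = probeLeak[2] * c_i)
    m440 <- matrix(e440 + background[1] / nPlanes, shape[1], shape[2])
    m520 <- matrix(e520 + background[2] / nPlanes, shape[1], shape[2])
    s440 <- apply(.noisyPlanes(m440, nPlanes, noise), c(2, 3), sum)
    s520 <- apply(.noisyPlanes(m520, nPlanes, noise), c(2, 3), sum)
    wells[[i]] <- list(
      concentrationMM = c_i,
      replicate = ((i - 1L) %% nReplicates) + 1L,
      nadph = .asSummed(s440, "nadph", NA_real_, nPlanes),
      fad = .asSummed(s520, "fad", NA_real_, nPlanes))
  }
  attr(wells, "truth") <- list(fluorophore = fluorophore, alpha = alpha,
                               background = background, noise = noise,
                               seed = seed,
                               countsPerMMPerPlane = countsPerMMPerPlane)
  wells
}

#' Simulate an ex vivo tissue-slice mosaic
#'
#' Generates per-tile acquisition sets whose tissue pixels carry the
#' programmed regional ORR: every tile belongs to a named region, all pixels
#' of a tile share the region's true ORR, and intensity (but not the ratio)
#' is given a random texture. Slices are imaged with 15-plane stacks in the
#' reference protocol.
#'
#' @param regionOrrs named numeric: region -> programmed true ORR.
#' @param grid a \linkS4class{TileGrid}.
#' @param regionAssignment named character: tile_id -> region; with a single
#'   region it may be omitted.
#' @param noise list(poisson, readSigma).
#' @param seed integer seed.
#' @param nPlanes planes per stack (default 15).
#' @param tissueIntensityPerPlane expected total counts per plane in tissue.
#' @param background numeric(2) per-channel background, summed scale.
#' @param alpha injected crosstalk coefficient.
#' @return list(tiles = named list of \linkS4class{AcquisitionSet},
#'   truth = list(regionAssignment, regionOrrs, alpha, background, seed)).
#' @export
simulateSliceMosaic <- function(regionOrrs, grid, regionAssignment = NULL,
                                noise = list(poisson = TRUE, readSigma = 2),
                                seed = 1L, nPlanes = 15L,
                                tissueIntensityPerPlane = 400,
                                background = c(0, 0), alpha = 0) {
  p <- grid@placement
  if (is.null(regionAssignment)) {
    if (length(regionOrrs) != 1L)
      stop("regionAssignment required with more than one region")
    regionAssignment <- setNames(rep(names(regionOrrs), nrow(p)), p$tile_id)
  }
  missing <- setdiff(p$tile_id, names(regionAssignment))
  if (length(missing))
    stop("tiles without region: ", paste(missing, collapse = ", "))
  set.seed(seed)
  ty <- grid@tileShape[1]; tx <- grid@tileShape[2]
  tiles <- list()
  for (i in seq_len(nrow(p))) {
    id <- p$tile_id[i]
    t <- regionOrrs[[regionAssignment[[id]]]]
    texture <- matrix(runif(ty * tx, 0.7, 1.3), ty, tx)
    itot <- tissueIntensityPerPlane * texture
    nadphTrue <- (1 - t) * itot
    fadTrue <- t * itot
    mkStack <- function(expected, role)
      ChannelStack(.noisyPlanes(expected, nPlanes, noise), role,
                   pixelSizeUm = NA_real_)
    tiles[[id]] <- AcquisitionSet(
      brightfield = mkStack(matrix(500, ty, tx), "brightfield"),
      nadph = mkStack(nadphTrue + background[1] / nPlanes, "nadph"),
      fad = mkStack(fadTrue + alpha * nadphTrue + background[2] / nPlanes,
                    "fad"),
      fieldId = id)
  }
  list(tiles = tiles,
       truth = list(regionAssignment = regionAssignment,
                    regionOrrs = regionOrrs, alpha = alpha,
                    background = unname(background), noise = noise,
                    seed = seed))
}
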