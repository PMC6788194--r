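labmap <- function(lab, ps = 1) new("LabelMap", labels = lab,
                                    nObjects = max(lab),
                                    pixelSizeUm = ps)

test_that("background is the median over the inverse mask and ignores objects", {
  lab <- matrix(0L, 6, 6); lab[2:4, 2:4] <- 1L
  img <- matrix(7, 6, 6); img[lab == 1L] <- 9999
  bg <- estimateBackground(summed(img), labmap(lab))
  expect_equal(bg@value, 7)
  expect_identical(bg@nBackgroundPixels, sum(lab == 0L))

  # median is robust to a stray bright background pixel
  img2 <- matrix(0, 2, 3)
  img2[1, ] <- c(1, 2, 100)
  lab2 <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 2, 3, byrow = TRUE)
  expect_equal(estimateBackground(summed(img2), labmap(lab2))@value, 2)

  # invariance: changing object pixels arbitrarily changes nothing
  img3 <- img; img3[lab == 1L] <- runif(sum(lab == 1L), 0, 1e6)
  expect_equal(estimateBackground(summed(img3), labmap(lab))@value, 7)

  # full mask is an error
  expect_error(estimateBackground(summed(img), labmap(matrix(1L, 6, 6))),
               "no background")
})

test_that("background estimate recovers the programmed offset under Poisson noise", {
  for (s in 1:5) {
    sim <- simulateAcquisition("AsPC-1-like", seed = 300 + s,
                               background = c(50, 50),
                               noise = list(poisson = TRUE, readSigma = 0))
    nadph <- sumStack(sim$acquisition@nadph)
    lab <- labmap(sim$truth$trueLabels, sim$truth$pixelSizeUm)
    est <- estimateBackground(nadph, lab)@value
    expect_lt(abs(est - 50) / 50, 0.02)
  }
})

test_that("background subtraction clamps at zero and checks roles", {
  img <- summed(matrix(c(100, 10, 30, 0), 2, 2), role = "fad")
  bg <- new("BackgroundEstimate", value = 30, channelRole = "fad",
            nBackgroundPixels = 10L)
  out <- subtractBackground(img, bg)
  expect_equal(pixels(out), matrix(c(70, 0, 0, 0), 2, 2))
  # zero background is the identity
  bg0 <- new("BackgroundEstimate", value = 0, channelRole = "fad",
             nBackgroundPixels = 10L)
  expect_equal(pixels(subtractBackground(img, bg0)), pixels(img))
  wrong <- new("BackgroundEstimate", value = 1, channelRole = "nadph",
               nBackgroundPixels = 10L)
  expect_error(subtractBackground(img, wrong), "mismatch")
})

test_that("crosstalk fit returns the exact ratio on noise-free standards", {
  wells <- simulateStandardCurve("nadh", c(0.05, 0.08, 0.1, 0.15, 0.2),
                                 alpha = 0.39, background = c(0, 0),
                                 noise = list(poisson = FALSE, readSigma = 0),
                                 seed = 1)
  cal <- estimateCrosstalk(wells)
  expect_equal(crosstalkAlpha(cal), 0.39, tolerance = 1e-12)

  # zero 520-band signal gives alpha = 0
  wells0 <- simulateStandardCurve("nadh", c(0.05, 0.1, 0.2), alpha = 0,
                                  background = c(0, 0),
                                  noise = list(poisson = FALSE,
                                               readSigma = 0), seed = 1)
  expect_equal(crosstalkAlpha(estimateCrosstalk(wells0)), 0)

  # fewer than 3 wells in range is an error
  expect_error(estimateCrosstalk(wells[1:3], restrictRangeMM = c(0.05, 0.06)),
               "at least 3")
})

test_that("crosstalk fit recovers a programmed coefficient under noise", {
  for (s in 1:5) {
    wells <- simulateStandardCurve("nadh",
                                   c(0.05, 0.07, 0.1, 0.13, 0.16, 0.2),
                                   alpha = 0.25, nReplicates = 3, seed = s)
    cal <- estimateCrosstalk(wells)
    expect_lt(abs(crosstalkAlpha(cal) - 0.25),
              max(3 * cal@fitStderr, 0.01))
  }
})

test_that("FAD correction applies cFAD = FAD - alpha * NAD(P)H with clamping", {
  nad <- summed(matrix(100, 2, 2), role = "nadph")
  mkf <- function(v) summed(matrix(v, 2, 2), role = "fad")
  expect_equal(pixels(correctFad(mkf(100), nad, 0.39))[1], 61)
  expect_equal(pixels(correctFad(mkf(39), nad, 0.39))[1], 0)
  expect_equal(pixels(correctFad(mkf(10), nad, 0.39))[1], 0)  # clamped, not -29
  # zero crosstalk is the identity
  expect_equal(pixels(correctFad(mkf(55), nad, 0)), pixels(mkf(55)))
  expect_error(correctFad(mkf(1), nad, 1.2), "alpha")
})

test_that("FAD wells emit nothing in the 440 band", {
  wells <- simulateStandardCurve("fad", c(0.05, 0.1, 0.2), alpha = 0.39,
                                 background = c(30, 30),
                                 noise = list(poisson = FALSE, readSigma = 0),
                                 seed = 1)
  conc <- vapply(wells, function(w) w$concentrationMM, numeric(1))
  m440 <- vapply(wells, function(w) mean(pixels(w$nadph)), numeric(1))
  expect_true(all(abs(m440 - 30) < 1e-9))  # background only
  m520 <- vapply(wells, function(w) mean(pixels(w$fad)), numeric(1))
  expect_true(all(m520[conc > 0] > 30))
})

test_that("interference screen passes clean probes and names failing channels", {
  mkwells <- function(leak) simulateStandardCurve(
    "probe", c(0.1, 0.5), probeLeak = leak, background = c(20, 20),
    noise = list(poisson = FALSE, readSigma = 0), seed = 1)
  ref <- c(10000, 10000)
  clean <- checkInterference(mkwells(c(0, 0)), ref)
  expect_true(clean$pass)
  expect_equal(clean$fraction440, 0)
  expect_equal(clean$fraction520, 0)

  leaky <- checkInterference(mkwells(c(0, 600)), ref)  # ~50% of ref in FAD band
  expect_false(leaky$pass)
  expect_identical(leaky$failedChannels, "fad")

  tiny <- checkInterference(mkwells(c(1, 1)), ref)  # ~1% in both bands
  expect_true(tiny$pass)
  expect_error(checkInterference(mkwells(c(0, 0))), "referenceLevels")
})

test_that("calibration JSON round-trips", {
  cal <- new("CrosstalkCalibration", alpha = 0.39, fitStderr = 0.004,
             concentrationRangeMM = c(0.05, 0.2), nPoints = 8L)
  path <- withr::local_tempfile(fileext = ".json")
  writeCalibration(cal, path)
  back <- readCalibration(path)
  expect_equal(crosstalkAlpha(back), 0.39)
  expect_identical(back@nPoints, 8L)
})
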