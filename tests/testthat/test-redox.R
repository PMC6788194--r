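test_that("pixel-wise ORR follows the defining ratio and validity rule", {
  nad <- summed(matrix(c(100, 0, 3, 0), 2, 2), "nadph")
  cf <- summed(matrix(c(0, 100, 1, 0), 2, 2), "fad")
  rm <- computeOrrMap(nad, cf)
  expect_equal(orrValues(rm)[1, 1], 0)
  expect_equal(orrValues(rm)[2, 1], 1)
  expect_equal(orrValues(rm)[1, 2], 0.25)
  expect_true(is.na(orrValues(rm)[2, 2]))   # zero denominator -> invalid
  expect_false(validMask(rm)[2, 2])
})

test_that("per-object statistics implement both averaging orders", {
  lab <- matrix(0L, 2, 3); lab[1, ] <- 1L
  lm <- new("LabelMap", labels = lab, nObjects = 1L, pixelSizeUm = 2)
  nad <- summed(matrix(c(1, 3, 1, 0, 0, 0), 2, 3, byrow = TRUE), "nadph")
  cf <- summed(matrix(c(1, 1, 9, 0, 0, 0), 2, 3, byrow = TRUE), "fad")
  rmap <- computeOrrMap(nad, cf)
  rec <- summarizeObjects(rmap, lm, nad, cf, fieldId = "f")
  expect_identical(nrow(rec), 1L)
  # pixel ratios are 0.5, 0.25, 0.9 -> median 0.5; overall = 11/16
  expect_equal(rec$median_orr, 0.5)
  expect_equal(rec$overall_orr, sum(c(1, 1, 9)) / sum(c(1, 3, 1, 1, 1, 9)))
  expect_equal(rec$area_um2, 3 * 4)

  # the two-pixel textbook case: ratio of means 1/3 vs mean of ratios 0.375
  lab2 <- matrix(1L, 1, 2)
  lm2 <- new("LabelMap", labels = lab2, nObjects = 1L, pixelSizeUm = 1)
  nad2 <- summed(matrix(c(1, 3), 1, 2), "nadph")
  cf2 <- summed(matrix(c(1, 1), 1, 2), "fad")
  rec2 <- summarizeObjects(computeOrrMap(nad2, cf2), lm2, nad2, cf2)
  expect_equal(rec2$overall_orr, 1 / 3)
  expect_equal(rec2$mean_orr, 0.375)

  # median over explicit pixel ORRs
  lab3 <- matrix(1L, 1, 3)
  lm3 <- new("LabelMap", labels = lab3, nObjects = 1L, pixelSizeUm = 1)
  nad3 <- summed(matrix(c(9, 8, 1), 1, 3), "nadph")
  cf3 <- summed(matrix(c(1, 2, 9), 1, 3), "fad")
  rec3 <- summarizeObjects(computeOrrMap(nad3, cf3), lm3, nad3, cf3)
  expect_equal(rec3$median_orr, 0.2)
})

test_that("objects with no valid pixels carry undefined statistics", {
  lab <- matrix(1L, 2, 2)
  lm <- new("LabelMap", labels = lab, nObjects = 1L, pixelSizeUm = 1)
  z <- summed(matrix(0, 2, 2))
  rec <- summarizeObjects(computeOrrMap(z, z), lm, z, z)
  expect_true(is.na(rec$median_orr))
  expect_true(is.na(rec$overall_orr))
  expect_identical(rec$n_valid_pixels, 0L)
})

test_that("ORR statistics are scale-invariant and monotone", {
  set.seed(5)
  n <- matrix(runif(64, 1, 100), 8, 8)
  f <- matrix(runif(64, 1, 100), 8, 8)
  base <- computeOrrMap(summed(n), summed(f))
  for (k in c(0.01, 3, 1e4)) {
    scaled <- computeOrrMap(summed(k * n), summed(k * f))
    expect_equal(orrValues(scaled), orrValues(base), tolerance = 1e-12)
  }
  # monotonicity at a pixel
  orrAt <- function(nv, fv) orrValues(computeOrrMap(summed(matrix(nv, 1, 1)),
                                                    summed(matrix(fv, 1, 1))))[1]
  expect_true(orrAt(10, 6) > orrAt(10, 5))
  expect_true(orrAt(11, 5) < orrAt(10, 5))
})

test_that("all ORR outputs stay within [0, 1] over randomized inputs", {
  set.seed(99)
  for (i in 1:25) {
    n <- matrix(runif(100, 0, 1000), 10, 10)
    f <- matrix(runif(100, 0, 1000), 10, 10)
    lab <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
    K <- max(lab)
    lm <- new("LabelMap", labels = lab, nObjects = as.integer(K),
              pixelSizeUm = 1)
    rmap <- computeOrrMap(summed(n), summed(f), minSignal = runif(1, 0, 50))
    v <- orrValues(rmap)[validMask(rmap)]
    expect_true(all(v >= 0 & v <= 1))
    rec <- summarizeObjects(rmap, lm, summed(n), summed(f))
    for (col in c("median_orr", "mean_orr", "overall_orr")) {
      x <- rec[[col]][!is.na(rec[[col]])]
      expect_true(all(x >= 0 & x <= 1))
    }
  }
})

test_that("computeOrrMap agrees with the double-loop reference", {
  set.seed(123)
  for (i in 1:30) {
    nr <- sample(3:20, 1); nc <- sample(3:20, 1)
    n <- matrix(runif(nr * nc, 0, 50), nr, nc)
    f <- matrix(runif(nr * nc, 0, 50), nr, nc)
    ms <- runif(1, 0, 10)
    got <- computeOrrMap(summed(n), summed(f), minSignal = ms)
    ref <- refOrrMap(n, f, ms)
    expect_identical(validMask(got), ref$valid)
    expect_equal(orrValues(got), ref$orr, tolerance = 1e-15)
  }
})

test_that("image median pools valid pixels as defined", {
  uni <- new("RedoxMap", orr = matrix(0.26, 4, 4), valid = matrix(TRUE, 4, 4),
             pixelSizeUm = 1)
  expect_equal(imageMedianOrr(uni), 0.26)
  half <- new("RedoxMap",
              orr = matrix(rep(c(0.2, 0.4), each = 8), 4, 4),
              valid = matrix(TRUE, 4, 4), pixelSizeUm = 1)
  expect_equal(imageMedianOrr(half), 0.3)
  none <- new("RedoxMap", orr = matrix(NA_real_, 2, 2),
              valid = matrix(FALSE, 2, 2), pixelSizeUm = 1)
  expect_error(imageMedianOrr(none), "no valid")
  # object restriction
  lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 1L
  lm <- new("LabelMap", labels = lab, nObjects = 1L, pixelSizeUm = 1)
  mixed <- new("RedoxMap",
               orr = matrix(0.9, 4, 4) - 0.8 * (lab > 0),
               valid = matrix(TRUE, 4, 4), pixelSizeUm = 1)
  expect_equal(imageMedianOrr(mixed, restrictToObjects = TRUE, labels = lm),
               0.1)
})

test_that("end-to-end recovery hits the programmed per-object medians", {
  sim <- simulateAcquisition("AsPC-1-like", seed = 77)
  res <- analyzeAcquisition(sim$acquisition)
  expect_identical(nrow(res$records), nrow(sim$truth$objects))
  expect_true(all(abs(res$records$median_orr -
                        sim$truth$objects$true_median_orr) < 0.02))
})
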