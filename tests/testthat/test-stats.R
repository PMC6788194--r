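test_that("the normality test reproduces frozen omnibus reference values", {
  # reference values computed independently from the published skewness and
  # kurtosis transforms (external implementation), frozen here
  x1 <- c(2.3, 1.9, 2.8, 3.1, 2.2, 2.0, 2.6, 3.3, 1.7, 2.4, 2.9, 2.1)
  r1 <- dagostinoPearsonTest(x1)
  expect_equal(r1$statistic, 0.9058827548, tolerance = 1e-9)
  expect_equal(r1$p.value, 0.6357554022, tolerance = 1e-8)
  expect_equal(r1$z.skew, 0.5010977374, tolerance = 1e-9)
  expect_equal(r1$z.kurt, -0.8091871306, tolerance = 1e-9)

  x2 <- c(0.12, 0.05, 0.31, 0.89, 0.02, 0.15, 0.44, 1.7, 0.08, 0.23)
  r2 <- dagostinoPearsonTest(x2)
  expect_equal(r2$statistic, 13.2804776644, tolerance = 1e-9)
  expect_equal(r2$p.value, 0.0013067151, tolerance = 1e-6)

  expect_error(dagostinoPearsonTest(1:5), "n >= 8")
})

test_that("the normality test rejects exponential samples and accepts Gaussian ones", {
  set.seed(31)
  rejectExp <- mean(replicate(200, dagostinoPearsonTest(rexp(40))$p.value) <= 0.05)
  expect_gt(rejectExp, 0.8)
  rejectNorm <- mean(replicate(200, dagostinoPearsonTest(rnorm(40))$p.value) <= 0.05)
  expect_lt(rejectNorm, 0.15)
})

test_that("star mapping follows the figure convention and preserves order", {
  expect_identical(pToStars(c(0.06, 0.05, 0.011, 0.01, 0.0051, 0.005,
                              0.0011, 0.001, 1e-9)),
                   c("ns", "*", "*", "**", "**", "***", "***", "****",
                     "****"))
  expect_identical(pToStars(0.003), "***")
  # order-preserving: more stars never at larger p
  p <- sort(runif(50))
  nstars <- nchar(gsub("ns", "", pToStars(p)))
  expect_true(all(diff(nstars) <= 0))
})

test_that("Dunn pairwise z-tests match frozen rank-arithmetic references", {
  d <- orrpipe:::.dunnPairwise(list(a = c(1.2, 2.3, 1.9, 2.8, 1.1),
                                    b = c(3.1, 4.0, 2.9, 3.5, 3.8),
                                    c = c(1.0, 1.4, 0.9, 1.3, 1.6)))
  expect_equal(d$z, c(-2.1920310217, 0.9192388155, 3.1112698372),
               tolerance = 1e-9)
  expect_equal(d$p_unadjusted,
               c(0.0283772667, 0.3579706726, 0.0018628463),
               tolerance = 1e-9)
})

test_that("the normality gate chooses the path and small groups force nonparametric", {
  set.seed(71)
  gauss <- list(a = rnorm(30, 1), b = rnorm(30, 1), c = rnorm(30, 1.2))
  cmpG <- compareGroups(gauss)
  expect_identical(cmpG@pathTaken, "anova_bonferroni")

  skewed <- list(a = rnorm(30, 1), b = rexp(30)^3, c = rnorm(30, 1.2))
  cmpS <- compareGroups(skewed)
  expect_identical(cmpS@pathTaken, "kruskalwallis_dunn")

  expect_warning(cmpSmall <- compareGroups(list(a = rnorm(5), b = rnorm(30))),
                 "too small")
  expect_identical(cmpSmall@pathTaken, "kruskalwallis_dunn")
})

test_that("identical groups earn no stars and order does not matter", {
  x <- c(1.3, 2.2, 0.9, 1.7, 2.8, 1.1, 2.0, 1.5, 2.4, 1.9, 1.2, 2.6)
  same <- suppressWarnings(compareGroups(list(a = x, b = x, c = x)))
  expect_true(all(same@pairwise$stars == "ns"))

  set.seed(17)
  g <- list(a = rnorm(20, 0), b = rnorm(20, 2), c = rnorm(20, 0.5))
  c1 <- compareGroups(g)
  c2 <- compareGroups(g[c("c", "a", "b")])
  expect_equal(c1@omnibusP, c2@omnibusP)
  key <- function(cmp) {
    pw <- cmp@pairwise
    nm <- unname(t(apply(pw[, c("group1", "group2")], 1, sort)))
    o <- order(nm[, 1], nm[, 2])
    list(pairs = nm[o, , drop = FALSE], p = pw$p_adjusted[o])
  }
  expect_equal(key(c1)$p, key(c2)$p, tolerance = 1e-12)
  expect_identical(key(c1)$pairs, key(c2)$pairs)
})

test_that("Dunn pairwise p-values are Bonferroni-adjusted in the result", {
  set.seed(23)
  skewed <- list(a = rexp(25)^2, b = rexp(25)^2 + 3, c = rexp(25)^2)
  cmp <- compareGroups(skewed)
  expect_identical(cmp@pathTaken, "kruskalwallis_dunn")
  raw <- orrpipe:::.dunnPairwise(cmp@groups)
  expect_equal(cmp@pairwise$p_adjusted,
               pmin(raw$p_unadjusted * nrow(raw), 1), tolerance = 1e-12)
})

test_that("size-ORR regression handles exact, constant and trending data", {
  area <- c(1e4, 2e4, 3e4, 4e4, 5e4)
  exact <- data.frame(area_um2 = area, median_orr = 0.5 - 1e-6 * area)
  f <- fitSizeOrr(exact)
  expect_equal(f@slope, -1e-6, tolerance = 1e-12)
  expect_equal(f@r, -1, tolerance = 1e-9)

  flat <- data.frame(area_um2 = area, median_orr = rep(0.3, 5))
  f2 <- fitSizeOrr(flat)
  expect_equal(f2@slope, 0, tolerance = 1e-12)
  expect_equal(f2@r, 0)

  expect_error(fitSizeOrr(data.frame(area_um2 = rep(1, 5),
                                     median_orr = runif(5))), "degenerate")
})

test_that("periphery-elevated cohorts show the negative size-ORR trend", {
  # rim-boosted ORR raises small objects' medians relative to large ones
  # only through geometry; the fitted slope must come out negative
  preset <- new("PhenotypePreset", name = "trend", trueMedianOrr = 0.15,
                orrSpread = 0.01, peripheryBoost = 0.15,
                objectRadiusUm = c(30, 70), nObjects = 8L)
  negatives <- 0
  for (s in 1:8) {
    recs <- do.call(rbind, lapply(1:2, function(f) {
      sim <- simulateAcquisition(preset, seed = 600 + 10 * s + f,
                                 fieldId = paste0("f", f))
      analyzeAcquisition(sim$acquisition)$records
    }))
    negatives <- negatives + (fitSizeOrr(recs)@slope < 0)
  }
  expect_gte(negatives, 8 * 0.95 - 1)  # >= 7 of 8 cohorts
})
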