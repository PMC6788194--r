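#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness test and the Anscombe-Glynn kurtosis
#' test into the omnibus statistic K2 = Z1^2 + Z2^2, referred to a
#' chi-squared distribution with 2 degrees of freedom. Requires n >= 8 for
#' the kurtosis normal approximation to be defined.
#'
#' @param x numeric sample.
#' @return list with elements \code{statistic} (K2), \code{p.value},
#'   \code{z.skew}, \code{z.kurt}, \code{n}.
#' @export
dagostinoPearsonTest <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) stop("zero-variance sample")
  # skewness transform (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  a <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(y / a + sqrt((y / a)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqrtB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtB1 * (2 / sqrtB1 + sqrt(1 + 4 / sqrtB1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- z1^2 + z2^2
  list(statistic = K2, p.value = pchisq(K2, df = 2, lower.tail = FALSE),
       z.skew = z1, z.kurt = z2, n = n)
}

#' Map an adjusted p-value to significance stars
#'
#' The figure-annotation convention: "*" for p <= 0.05, "**" for p <= 0.01,
#' "***" for p <= 0.005, "****" for p <= 0.001, "ns" otherwise. A pure,
#' order-preserving function of p.
#'
#' @param p numeric vector of (adjusted) p-values.
#' @return character vector of star strings.
#' @export
pToStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 0.001) "****"
    else if (pi <= 0.005) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else "ns"
  }, character(1))
}

# Dunn's pairwise z-tests on joint ranks, with tie correction; two-sided
# p-values, unadjusted (adjustment applied by the caller)
.dunnPairwise <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(values)
  r <- rank(values)
  meanRank <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  nm <- names(groups)
  combs <- utils::combn(nm, 2)
  res <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                    z = NA_real_, p_unadjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (meanRank[[a]] - meanRank[[b]]) / se
    res$z[i] <- z
    res$p_unadjusted[i] <- 2 * pnorm(-abs(z))
  }
  res
}

#' Normality-gated multi-group comparison with star annotation
#'
#' Each group is first screened with the D'Agostino-Pearson omnibus test. If
#' every group passes at \code{alphaNormality}, the parametric branch is
#' taken: one-way ANOVA with Bonferroni-adjusted pairwise t-tests (pooled
#' SD). If any group fails — the omnibus ANOVA assumes all groups are
#' approximately normal — the nonparametric branch is taken: Kruskal-Wallis
#' with Dunn's pairwise post hoc tests, Bonferroni-adjusted. Groups too small
#' for the normality test (n < 8) force the nonparametric branch with a
#' warning.
#'
#' @param groups named list of numeric samples (>= 2 groups).
#' @param alphaNormality significance level of the normality gate.
#' @return A \linkS4class{GroupComparison}.
#' @export
compareGroups <- function(groups, alphaNormality = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  ns <- lengths(groups)
  tooSmall <- ns < 8L
  normP <- rep(NA_real_, length(groups))
  names(normP) <- names(groups)
  for (i in seq_along(groups)) {
    if (!tooSmall[i]) normP[i] <- dagostinoPearsonTest(groups[[i]])$p.value
  }
  if (any(tooSmall)) {
    warning("group(s) too small for the normality test (n < 8): ",
            paste(names(groups)[tooSmall], collapse = ", "),
            "; taking the nonparametric path")
    parametric <- FALSE
  } else {
    parametric <- all(normP > alphaNormality)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  if (parametric) {
    fit <- aov(values ~ g)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    pt <- pairwise.t.test(values, g, p.adjust.method = "bonferroni",
                          pool.sd = TRUE)
    pm <- pt$p.value
    combs <- utils::combn(names(groups), 2)
    padj <- vapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      if (!is.null(pm) && b %in% rownames(pm) && a %in% colnames(pm) &&
          !is.na(pm[b, a])) pm[b, a] else pm[a, b]
    }, numeric(1))
    pw <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                     p_adjusted = padj, stringsAsFactors = FALSE)
    path <- "anova_bonferroni"
  } else {
    kt <- kruskal.test(values, g)
    omnibus <- kt$p.value
    dn <- .dunnPairwise(groups)
    pw <- data.frame(group1 = dn$group1, group2 = dn$group2,
                     p_adjusted = pmin(p.adjust(dn$p_unadjusted,
                                                "bonferroni"), 1),
                     stringsAsFactors = FALSE)
    path <- "kruskalwallis_dunn"
  }
  pw$stars <- pToStars(pw$p_adjusted)
  new("GroupComparison", groups = groups, normalityP = normP,
      pathTaken = path, omnibusP = unname(omnibus), pairwise = pw)
}

#' Descriptive regression of per-object ORR on object size
#'
#' Ordinary least squares of the per-object median ORR on object area (um^2)
#' plus the Pearson correlation. Reported as a qualitative indication of the
#' size-ORR relation (periphery-elevated redox makes smaller objects read
#' higher); no p-value is attached by default.
#'
#' @param records data.frame of object records with columns
#'   \code{area_um2} and \code{median_orr}.
#' @return A \linkS4class{SizeOrrFit}.
#' @export
fitSizeOrr <- function(records) {
  d <- records[stats::complete.cases(records[, c("area_um2", "median_orr")]), ]
  if (nrow(d) < 3L) stop("need at least 3 objects with defined ORR")
  if (sd(d$area_um2) == 0) stop("degenerate fit: zero-variance sizes")
  fit <- lm(median_orr ~ area_um2, data = d)
  r <- if (sd(d$median_orr) == 0) 0 else cor(d$area_um2, d$median_orr)
  new("SizeOrrFit", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), r = r, n = nrow(d))
}

#' Serialize a GroupComparison to JSON
#'
#' @param cmp a \linkS4class{GroupComparison}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeComparison <- function(cmp, path) {
  jsonlite::write_json(list(
    path_taken = cmp@pathTaken,
    omnibus_p = cmp@omnibusP,
    normality_p = as.list(cmp@normalityP),
    pairwise = cmp@pairwise
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
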