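#' Wilcoxon rank-sum test for a two-batch feature
#'
#' Two-sided rank-sum test using the tie-corrected normal approximation
#' (via [stats::wilcox.test()]). Defined for exactly two batch levels;
#' designs with more levels are an unsupported-design error (the k-sample
#' Anderson-Darling test covers those).
#'
#' @param y numeric feature vector.
#' @param labels batch factor with exactly 2 levels.
#' @return A list with `test`, `statistic` (W), `pValue`.
#' @export
wrsTest <- function(y, labels) {
  g <- twoLevelCheck(y, labels, "Wilcoxon rank-sum")
  ht <- stats::wilcox.test(y[g == levels(g)[1L]], y[g == levels(g)[2L]],
    alternative = "two.sided", exact = FALSE, correct = TRUE)
  list(test = "wrs", statistic = unname(ht$statistic),
    pValue = ht$p.value)
}

#' Two-sample Kolmogorov-Smirnov test for a two-batch feature
#'
#' Two-sided statistic (supremum of the ECDF difference) with the
#' asymptotic p-value (via [stats::ks.test()]).
#'
#' @inheritParams wrsTest
#' @return A list with `test`, `statistic` (D), `pValue`.
#' @export
ksTest <- function(y, labels) {
  g <- twoLevelCheck(y, labels, "Kolmogorov-Smirnov")
  ht <- suppressWarnings(stats::ks.test(y[g == levels(g)[1L]],
    y[g == levels(g)[2L]], alternative = "two.sided", exact = FALSE))
  list(test = "ks", statistic = unname(ht$statistic), pValue = ht$p.value)
}

twoLevelCheck <- function(y, labels, what) {
  g <- droplevels(as.factor(labels))
  if (nlevels(g) != 2L)
    bevalStop(what, " requires exactly 2 batch levels (got ", nlevels(g),
      "); use the k-sample Anderson-Darling test",
      class = "batcheval_unsupported")
  if (length(y) != length(g))
    bevalStop("y and labels differ in length", class = "batcheval_alignment")
  g
}

#' k-sample Anderson-Darling test (Scholz-Stephens)
#'
#' The rank-based k-sample Anderson-Darling statistic in its midrank
#' (tie-adjusted) version, standardized by its exact finite-sample null
#' variance. The p-value interpolates the published table of critical
#' values of the standardized statistic at significance levels 0.25, 0.10,
#' 0.05, 0.025, 0.01 (quadratic fit of log significance against the
#' critical value, the established interpolation for this test) and is
#' floored at 0.001: far-out statistics are reported as p = 0.001 rather
#' than an extrapolated near-zero value, and statistics far below the table
#' extrapolate above 0.25 (capped at 1).
#'
#' @param y numeric feature vector.
#' @param labels batch factor with >= 2 levels, each level with >= 2
#'   observations.
#' @return A list with `test`, `statistic` (the standardized statistic),
#'   `A2` (the raw midrank statistic), `pValue`, `k`.
#' @examples
#' set.seed(1)
#' adKSampleTest(rnorm(60), rep(c("a", "b", "c"), 20))
#' @export
adKSampleTest <- function(y, labels) {
  g <- droplevels(as.factor(labels))
  k <- nlevels(g)
  if (k < 2L)
    bevalStop("need >= 2 batch levels", class = "batcheval_validation")
  ns <- as.integer(table(g))
  if (any(ns < 2L))
    bevalStop("every batch level needs >= 2 observations",
      class = "batcheval_validation")
  if (anyNA(y) || any(!is.finite(y)))
    bevalStop("y must be finite", class = "batcheval_validation")
  N <- length(y)
  z <- sort(y)
  r <- rle(z)
  zstar <- r$values
  lj <- r$lengths
  if (length(zstar) < 2L)
    bevalStop("all pooled values are identical",
      class = "batcheval_degenerate")
  Bj <- cumsum(lj) - lj / 2
  denom <- Bj * (N - Bj) - N * lj / 4
  keep <- denom > 0
  gi <- as.integer(g)
  a2 <- 0
  for (i in seq_len(k)) {
    yi <- y[gi == i]
    cnt <- countAt(yi, zstar)
    Mij <- cumsum(cnt) - cnt / 2
    term <- (lj / N) * (N * Mij - ns[i] * Bj)^2 / denom
    a2 <- a2 + sum(term[keep]) / ns[i]
  }
  a2 <- a2 * (N - 1) / N
  sig2 <- adNullVariance(N, k, ns)
  tk <- (a2 - (k - 1)) / sqrt(sig2)
  list(test = "ad", statistic = tk, A2 = a2,
    pValue = adPValue(tk, k - 1L), k = k)
}

## Count occurrences of each zstar value in x (zstar sorted, from the
## pooled sample, so every x matches some zstar exactly).
countAt <- function(x, zstar) {
  tabulate(findInterval(x, zstar), length(zstar))
}

## Exact null variance of the k-sample statistic (finite-N formula).
adNullVariance <- function(N, k, ns) {
  H <- sum(1 / ns)
  hh <- sum(1 / seq_len(N - 1))
  ## G = sum_{i=1}^{N-2} sum_{j=i+1}^{N-1} 1 / ((N - i) j), computed in
  ## O(N) via partial harmonic sums.
  Hn <- cumsum(1 / seq_len(N - 1)) # Hn[t] = sum_{j<=t} 1/j
  ip <- 2:(N - 1) # i' = N - i
  G <- sum((Hn[N - 1] - Hn[N - ip]) / ip)
  a <- (4 * G - 6) * (k - 1) + (10 - 6 * G) * H
  b <- (2 * G - 4) * k^2 + 8 * hh * k +
    (2 * G - 14 * hh - 4) * H - 8 * hh + 4 * G - 6
  cc <- (6 * hh + 2 * G - 2) * k^2 + (4 * hh - 4 * G + 6) * k +
    (2 * hh - 6) * H + 4 * hh
  d <- (2 * hh + 6) * k^2 - 4 * hh * k
  (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
}

## Published critical values t_m(alpha) of the standardized statistic,
## t_m = b0 + b1 / sqrt(m) + b2 / m with m = k - 1.
AD_TABLE <- list(
  sig = c(0.25, 0.10, 0.05, 0.025, 0.01),
  b0 = c(0.675, 1.281, 1.645, 1.960, 2.326),
  b1 = c(-0.245, 0.250, 0.678, 1.149, 1.822),
  b2 = c(-0.105, -0.305, -0.362, -0.391, -0.396))

AD_P_FLOOR <- 0.001

adPValue <- function(tk, m) {
  tm <- AD_TABLE$b0 + AD_TABLE$b1 / sqrt(m) + AD_TABLE$b2 / m
  co <- stats::lm.fit(cbind(1, tm, tm^2), log(AD_TABLE$sig))$coefficients
  qf <- function(t) co[1] + co[2] * t + co[3] * t^2
  ## the quadratic is only trusted inside the table's range; beyond the
  ## ends it is continued linearly with the endpoint slope, keeping the
  ## mapping monotone for extreme statistics
  lp <- if (tk < tm[1L]) {
    qf(tm[1L]) + (co[2] + 2 * co[3] * tm[1L]) * (tk - tm[1L])
  } else if (tk > tm[length(tm)]) {
    tmx <- tm[length(tm)]
    qf(tmx) + (co[2] + 2 * co[3] * tmx) * (tk - tmx)
  } else qf(tk)
  min(1, max(AD_P_FLOOR, exp(unname(lp))))
}

#' Apply univariate batch tests feature-wise
#'
#' Runs the requested tests on every feature of a
#' [BatchExperiment-class] and records the rejection indicator at `alpha`.
#' With more than two batch levels the two-sample tests (wrs, ks) are
#' reported as unsupported rows with NA statistics, mirroring the practice
#' of falling back to the k-sample Anderson-Darling test alone.
#'
#' @param x a [BatchExperiment-class].
#' @param tests subset of `c("wrs", "ks", "ad")`.
#' @param alpha significance level for the rejection column (default 0.05).
#' @return A data.frame with one row per (feature, test): `feature`,
#'   `test`, `statistic`, `pValue`, `reject`, `status`.
#' @examples
#' be <- simulateBatchData(50, nFeatures = 2, seed = 7)
#' featureTestSuite(be)
#' @export
featureTestSuite <- function(x, tests = c("wrs", "ks", "ad"),
                             alpha = 0.05) {
  tests <- match.arg(tests, several.ok = TRUE)
  y <- featureValues(x)
  g <- droplevels(batchLabels(x))
  k <- nlevels(g)
  rows <- list()
  for (j in seq_len(ncol(y))) {
    for (tt in tests) {
      row <- data.frame(feature = colnames(y)[j], test = tt,
        statistic = NA_real_, pValue = NA_real_, reject = NA,
        status = "ok", row.names = NULL)
      if (tt %in% c("wrs", "ks") && k > 2L) {
        row$status <- "unsupported: > 2 batch levels"
      } else {
        r <- switch(tt, wrs = wrsTest(y[, j], g), ks = ksTest(y[, j], g),
          ad = adKSampleTest(y[, j], g))
        row$statistic <- r$statistic
        row$pValue <- r$pValue
        row$reject <- r$pValue < alpha
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
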