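test_that("reference coding recovers group means", {
  set.seed(31)
  g <- factor(rep(c("ref", "alt"), each = 4000), levels = c("ref", "alt"))
  y <- rnorm(8000) + ifelse(g == "ref", 1.0, 3.5)
  fit <- fitBatchModel(y, g)
  expect_equal(unname(fit$beta), c(1.0, 2.5), tolerance = 0.1)
  expect_identical(fit$referenceLevel, "ref")
})

test_that("an exact indicator outcome hits the degenerate-fit path", {
  g <- factor(rep(c("a", "b"), each = 5))
  y <- as.numeric(g == "b")
  expect_error(fitBatchModel(y, g), "degenerate")
})

test_that("closed-form grouped sandwich equals lm + sandwich::vcovHC", {
  set.seed(32)
  for (k in c(2, 3)) {
    for (hct in c("HC0", "HC1", "HC2", "HC3")) {
      g <- factor(rep(paste0("g", 1:k), times = sample(5:12, k)))
      y <- rnorm(length(g), sd = as.integer(g)) # heteroskedastic
      fit <- fitBatchModel(y, g, hcType = hct)
      fast <- batcheval:::resiPointGrouped(y, as.integer(g), k,
        hcType = hct)
      slow <- resiPoint(fit)
      expect_equal(as.vector(fast$perCoefficient),
        unname(slow$perCoefficient), tolerance = 1e-10, info = hct)
      expect_equal(fast$overall, slow$overall, tolerance = 1e-10,
        info = hct)
    }
  }
})

test_that("sandwich variance tracks the nonparametric group-mean variance", {
  ## strongly heteroskedastic two-group data: the robust slope variance
  ## must match a direct Monte-Carlo estimate of var(mean2 - mean1)
  set.seed(33)
  n1 <- 40; n2 <- 120; s1 <- 0.5; s2 <- 3
  draws <- replicate(3000, mean(rnorm(n2, sd = s2)) -
    mean(rnorm(n1, sd = s1)))
  target <- var(draws)
  vs <- replicate(300, {
    g <- factor(rep(c("a", "b"), c(n1, n2)))
    y <- c(rnorm(n1, sd = s1), rnorm(n2, sd = s2))
    fitBatchModel(y, g)$robustCov[2, 2]
  })
  expect_lt(abs(mean(vs) - target) / target, 0.15)
})

test_that("truncation at zero and the d/2 large-n limit", {
  ## |z| <= 1 truncates to exactly zero
  fit <- list(beta = c(0, 0.05), robustCov = diag(c(1, 0.01)), n = 50)
  expect_identical(unname(resiPoint(fit)$perCoefficient), 0)
  ## balanced two-group standardized difference d -> S = d/2
  set.seed(34)
  n <- 1e5
  g <- factor(rep(c("a", "b"), each = n / 2))
  y <- rnorm(n) + ifelse(g == "b", 1, 0) # d = 1
  s <- resiPoint(fitBatchModel(y, g))$perCoefficient
  expect_equal(unname(s), 0.5, tolerance = 0.02)
})

test_that("overall and per-coefficient indices are consistent (g = 2)", {
  be <- simulateBatchData(200, nFeatures = 5, seed = 35)
  tab <- resiTable(be, nBoot = 0)
  ## positive excess: identical magnitudes; negative excess: the truncated
  ## per-coefficient index is exactly zero while the overall goes negative
  expect_equal(pmax(tab$overall, 0), abs(tab$resi), tolerance = 1e-10)
  be0 <- simulateBatchData(200, nFeatures = 20, addBatch = FALSE,
    seed = 36)
  tab0 <- resiTable(be0, nBoot = 0)
  neg <- tab0$overall < 0
  expect_true(any(neg))
  expect_true(all(tab0$resi[neg] == 0))
})

test_that("the index is invariant to affine rescaling of the feature", {
  set.seed(36)
  g <- factor(rep(c("a", "b"), each = 60))
  y <- rnorm(120) + ifelse(g == "b", 0.7, 0)
  s1 <- resiPoint(fitBatchModel(y, g))$perCoefficient
  s2 <- resiPoint(fitBatchModel(5 - 3 * y, g))$perCoefficient
  expect_equal(unname(s1), -unname(s2), tolerance = 1e-10)
  expect_equal(abs(unname(s1)), abs(unname(s2)), tolerance = 1e-12)
})

test_that("bootstrap intervals are deterministic given a seed", {
  set.seed(37)
  g <- factor(rep(c("a", "b"), each = 40))
  y <- rnorm(80) + ifelse(g == "b", 0.5, 0)
  ci1 <- resiBootstrapCi(y, g, nBoot = 100, seed = 5)
  ci2 <- resiBootstrapCi(y, g, nBoot = 100, seed = 5)
  expect_identical(ci1, ci2)
  expect_lte(ci1$perCoefficient[1, "low"], ci1$perCoefficient[1, "high"])
})

test_that("interval width shrinks roughly as 1/sqrt(n)", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    be <- simulateBatchData(n, nFeatures = 1, addBatch = FALSE,
      seed = 38 + n)
    ci <- resiBootstrapCi(featureValues(be)[, 1], batchLabels(be),
      nBoot = 300, seed = 1)
    diff(ci$perCoefficient[1, ])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], widths[1] / 2)
})

test_that("bootstrap intervals cover the long-run point estimate", {
  ## moderate-effect calibration: coverage of the large-n limit d/2
  set.seed(39)
  n <- 150; d <- 1.2
  hits <- vapply(1:120, function(k) {
    g <- factor(rep(c("a", "b"), each = n / 2))
    y <- rnorm(n) + ifelse(g == "b", d, 0)
    ci <- resiBootstrapCi(y, g, nBoot = 200,
      seed = iterationSeed(40, k))
    ci$perCoefficient[1, "low"] <= d / 2 &&
      d / 2 <= ci$perCoefficient[1, "high"]
  }, logical(1))
  expect_gte(mean(hits), 0.85) # 95% nominal, finite-n percentile interval
})

test_that("per-feature tables preserve order and record degeneracies", {
  be <- simulateBatchData(60, nFeatures = 20, seed = 41)
  tab <- resiTable(be, nBoot = 0)
  expect_equal(nrow(tab), 20)
  expect_identical(tab$feature,
    colnames(featureValues(be)))
  ## inject a constant feature: degenerate, recorded not fatal
  y <- featureValues(be); y[, 2] <- 7
  be2 <- BatchExperiment(y, batchLabels(be))
  tab2 <- resiTable(be2, nBoot = 0)
  expect_match(tab2$status[2], "degenerate")
  expect_true(is.na(tab2$resi[2]))
  expect_identical(tab2$status[-2], rep("ok", 19))
})
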