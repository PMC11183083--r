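test_that("every metric matches the independent per-pair scalar oracle", {
  set.seed(21)
  y <- matrix(abs(rnorm(5 * 4)) + 0.2, 5, 4)
  for (metric in c("euclidean", "chord", "clark", "gower", "jaccard",
                   "mahalanobis")) {
    skip_msg <- NULL
    d <- featureDist(y, metric, transform = "none")
    expect_equal(unname(as.matrix(d)), oracleDistMatrix(y, metric),
      tolerance = 1e-10, info = metric)
  }
})

test_that("basic identities: identical rows, 3-4-5, single feature", {
  y <- rbind(c(3, 4), c(0, 0), c(3, 4))
  d <- as.matrix(featureDist(y + 1e-9, "euclidean"))
  expect_equal(d[1, 2], 5, tolerance = 1e-6)
  expect_equal(d[1, 3], 0, tolerance = 1e-12)
  for (metric in c("euclidean", "chord", "clark", "gower", "jaccard")) {
    dd <- as.matrix(featureDist(abs(y) + 1, metric, transform = "none"))
    expect_equal(dd[1, 3], 0, tolerance = 1e-12, info = metric)
  }
  y1 <- matrix(c(1.5, -0.5, 3), 3, 1)
  d1 <- as.matrix(featureDist(y1, "euclidean"))
  expect_equal(d1[1, 2], 2)
  expect_equal(d1[2, 3], 3.5)
})

test_that("metric properties hold on random data", {
  set.seed(22)
  for (rep in 1:3) {
    y <- matrix(rnorm(8 * 5), 8, 5)
    for (metric in c("euclidean", "chord", "clark", "gower", "jaccard")) {
      d <- as.matrix(featureDist(y, metric, transform = "required"))
      expect_true(all(d >= 0), info = metric)
      expect_equal(d, t(d), info = metric)
      expect_true(all(diag(d) == 0), info = metric)
    }
  }
  ## chord is invariant to positive per-sample rescaling
  y <- matrix(abs(rnorm(24)) + 0.5, 6, 4)
  sc <- y * runif(6, 0.5, 4)
  expect_equal(as.matrix(featureDist(y, "chord", transform = "none")),
    as.matrix(featureDist(sc, "chord", transform = "none")),
    tolerance = 1e-10)
  ## quantitative jaccard lives in [0,1] and is monotone in Bray-Curtis
  d <- as.matrix(featureDist(y, "jaccard", transform = "none"))
  expect_true(all(d >= 0 & d <= 1))
  b <- sum(abs(y[1, ] - y[2, ])) / sum(y[1, ] + y[2, ])
  expect_equal(d[1, 2], 2 * b / (1 + b), tolerance = 1e-12)
})

test_that("mahalanobis equals euclidean under identity covariance", {
  set.seed(23)
  y <- matrix(rnorm(40 * 3), 40, 3)
  ## whiten so the sample covariance is exactly the identity
  z <- y %*% solve(chol(cov(y)))
  expect_equal(as.matrix(featureDist(z, "mahalanobis")),
    as.matrix(featureDist(z, "euclidean")), tolerance = 1e-8)
})

test_that("singular covariance raises an explicit error", {
  set.seed(24)
  base <- matrix(rnorm(10 * 2), 10, 2)
  y <- cbind(base, base[, 1] + 2 * base[, 2]) # exactly collinear
  expect_error(featureDist(y, "mahalanobis"), "singular covariance")
  ## more features than samples
  y2 <- matrix(rnorm(4 * 6), 4, 6)
  expect_error(featureDist(y2, "mahalanobis"), "singular covariance")
  ## ridge rescues it
  expect_s4_class(featureDist(y, "mahalanobis", ridge = 1e-6),
    "DistanceMatrix")
})

test_that("exponential transform: closed forms, monotonicity, overflow", {
  expect_equal(expTransform(matrix(0, 2, 2)), matrix(1, 2, 2))
  expect_equal(expTransform(matrix(log(2), 1, 1))[1, 1], 2)
  x <- matrix(rnorm(20), 5, 4); yy <- x + abs(rnorm(20)) + 0.1
  expect_true(all(expTransform(x) < expTransform(yy)))
  big <- matrix(c(1, 800), 1, 2,
    dimnames = list("s", c("ok", "huge")))
  expect_error(expTransform(big), "huge")
  be <- makeToyExperiment()
  expect_equal(featureValues(expTransform(be)), exp(featureValues(be)))
})

test_that("transform modes gate positivity as documented", {
  y <- matrix(rnorm(30), 10, 3) # signed data
  expect_s4_class(featureDist(y, "clark"), "DistanceMatrix") # required
  expect_error(featureDist(y, "clark", transform = "none"),
    "strictly positive")
  ## 'all' changes euclidean, 'required' does not
  d0 <- as.matrix(featureDist(y, "euclidean", transform = "required"))
  d1 <- as.matrix(featureDist(y, "euclidean", transform = "all"))
  expect_gt(max(abs(d0 - d1)), 0)
})

test_that("clark normalization switch rescales by sqrt(m)", {
  y <- matrix(abs(rnorm(20)) + 0.5, 5, 4)
  dn <- as.matrix(featureDist(y, "clark", transform = "none"))
  du <- as.matrix(featureDist(y, "clark", transform = "none",
    clarkNormalize = FALSE))
  expect_equal(du, dn * 2, tolerance = 1e-12) # sqrt(4) = 2
})

test_that("gower drops zero-range columns from the average", {
  y <- cbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(0, 1, 0, 2))
  d <- as.matrix(featureDist(y, "gower", transform = "none"))
  ## average over the two informative columns only
  expect_equal(d[1, 2], mean(c(1 / 3, 1 / 2)), tolerance = 1e-12)
})
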