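test_that("rank-sum: identical samples, exact-enumeration oracle", {
  y <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  expect_gt(wrsTest(y, g)$pValue, 0.9)
  set.seed(51)
  for (rep in 1:5) {
    x1 <- rnorm(4); x2 <- rnorm(4) + runif(1, 0, 2)
    pExact <- oracleExactWrsP(x1, x2)
    pApprox <- wrsTest(c(x1, x2), g)$pValue
    ## normal approximation with continuity correction at n1=n2=4
    expect_lt(abs(pApprox - pExact), 0.12)
    expect_equal(pApprox < 0.2, pExact < 0.2 ||
      abs(pExact - 0.2) < 0.12, info = "coarse decision agreement")
  }
})

test_that("ks: closed forms and the ECDF-sweep oracle", {
  g <- rep(c("a", "b"), each = 5)
  same <- rep(1:5, 2)
  expect_equal(ksTest(same, g)$statistic, 0) # identical samples
  disjoint <- c(1:5, 11:15)
  expect_equal(ksTest(disjoint, g)$statistic, 1)
  set.seed(52)
  for (rep in 1:5) {
    x1 <- rnorm(6); x2 <- rnorm(7, 0.5)
    gg <- rep(c("a", "b"), c(6, 7))
    expect_equal(ksTest(c(x1, x2), gg)$statistic,
      oracleKsStat(x1, x2), tolerance = 1e-12)
  }
})

test_that("two-sample tests refuse designs with more than two batches", {
  y <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  expect_error(wrsTest(y, g), "exactly 2")
  expect_error(ksTest(y, g), "exactly 2")
  expect_silent(adKSampleTest(y, g))
})

test_that("anderson-darling reproduces independently computed statistics", {
  ## four-laboratory water-quality data; standardized statistic verified
  ## against an independent implementation (and the published value 4.48)
  y1 <- c(38.7, 41.5, 43.8, 44.5, 45.5, 46.0, 47.7, 58.0)
  y2 <- c(39.2, 39.3, 39.7, 41.4, 41.8, 42.9, 43.3, 45.8)
  y3 <- c(34.0, 35.0, 39.0, 40.0, 43.0, 43.0, 44.0, 45.0)
  y4 <- c(34.0, 34.8, 34.8, 35.4, 37.2, 37.8, 41.2, 42.8)
  r <- adKSampleTest(c(y1, y2, y3, y4), rep(1:4, each = 8))
  expect_equal(r$statistic, 4.4797806271, tolerance = 1e-9)
  expect_equal(r$A2, 8.3926093268, tolerance = 1e-9)
  expect_lt(r$pValue, 0.01)
  expect_gt(r$pValue, 0.0005)
  ## a two-sample case frozen from the same independent implementation
  set.seed(9); y5 <- rnorm(30)
  r2 <- adKSampleTest(y5, rep(1:2, 15))
  expect_equal(r2$statistic, 2.7301099106, tolerance = 1e-9)
  expect_lt(abs(r2$pValue - 0.0249), 0.005)
})

test_that("anderson-darling handles identical samples and the p floor", {
  y <- rep(c(1.2, 3.4, 5.6, 7.8), 2)
  g <- rep(c("a", "b"), each = 4) # the two samples hold identical values
  r <- adKSampleTest(y, g)
  expect_lt(r$statistic, 0)
  expect_gt(r$pValue, 0.25)
  ## gigantic separation floors the p-value rather than reporting 0
  r2 <- adKSampleTest(c(rnorm(50), rnorm(50) + 50),
    rep(c("a", "b"), each = 50))
  expect_identical(r2$pValue, 0.001)
  expect_error(adKSampleTest(rep(1, 10), rep(c("a", "b"), 5)),
    "identical")
  expect_error(adKSampleTest(rnorm(3), c("a", "a", "b")),
    ">= 2 observations")
})

test_that("anderson-darling decisions agree with a permutation null", {
  set.seed(53)
  agree <- vapply(1:40, function(k) {
    n <- 40
    y <- rnorm(n) + rep(c(0, runif(1, 0, 1)), each = n / 2)
    g <- rep(c("a", "b"), each = n / 2)
    obs <- adKSampleTest(y, g)
    perm <- vapply(1:200, function(b)
      adKSampleTest(y, sample(g))$statistic, numeric(1))
    pPerm <- (1 + sum(perm >= obs$statistic)) / 201
    (obs$pValue < 0.05) == (pPerm < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})

test_that("rank tests are invariant to monotone transforms", {
  set.seed(54)
  y <- rnorm(40); g <- rep(c("a", "b"), 20)
  expect_equal(wrsTest(y, g)$pValue, wrsTest(exp(y), g)$pValue,
    tolerance = 1e-12)
  expect_equal(ksTest(y, g)$statistic, ksTest(exp(y), g)$statistic,
    tolerance = 1e-12)
  expect_equal(adKSampleTest(y, g)$statistic,
    adKSampleTest(exp(y), g)$statistic, tolerance = 1e-9)
})

test_that("the suite shapes rows per (feature, test) and flags unsupported", {
  be <- simulateBatchData(50, nFeatures = 20, seed = 55)
  tab <- featureTestSuite(be)
  expect_equal(nrow(tab), 60)
  expect_setequal(unique(tab$test), c("wrs", "ks", "ad"))
  expect_true(all(tab$status == "ok"))
  ## many batch levels: only ad runs
  be14 <- simulateBatchData(280, nFeatures = 2, nGroups = 14, seed = 56)
  tab14 <- featureTestSuite(be14)
  expect_true(all(is.na(tab14$pValue[tab14$test %in% c("wrs", "ks")])))
  expect_match(tab14$status[tab14$test == "wrs"][1], "unsupported")
  expect_true(all(!is.na(tab14$pValue[tab14$test == "ad"])))
})

test_that("null rejection rates sit near the nominal level", {
  set.seed(57)
  rej <- matrix(NA, 150, 3, dimnames = list(NULL, c("wrs", "ks", "ad")))
  for (k in 1:150) {
    y <- rnorm(60); g <- rep(c("a", "b"), 30)
    rej[k, "wrs"] <- wrsTest(y, g)$pValue < 0.05
    rej[k, "ks"] <- ksTest(y, g)$pValue < 0.05
    rej[k, "ad"] <- adKSampleTest(y, g)$pValue < 0.05
  }
  for (tt in colnames(rej)) {
    rate <- mean(rej[, tt])
    expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
  }
})
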