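test_that("gower centering: zeros, zero row sums, hand-computed oracle", {
  expect_equal(gowerCenter(matrix(0, 4, 4)), matrix(0, 4, 4))
  be <- makeToyExperiment(n = 12, seed = 3)
  G <- gowerCenter(featureDist(be, "euclidean"))
  expect_lt(max(abs(rowSums(G))), 1e-10 * 12)
  expect_equal(G, t(G), tolerance = 1e-12)
  ## direct C A C arithmetic on a small printed distance matrix
  d <- matrix(c(0, 1, 2, 3,
                1, 0, 1.5, 2.5,
                2, 1.5, 0, 1,
                3, 2.5, 1, 0), 4, 4)
  a <- -0.5 * d^2
  cmat <- diag(4) - matrix(1 / 4, 4, 4)
  expect_equal(gowerCenter(d), cmat %*% a %*% cmat, tolerance = 1e-12)
})

test_that("hat matrix has the closed block form and projection algebra", {
  h1 <- hatMatrix(rep("a", 5))
  expect_equal(h1, matrix(1 / 5, 5, 5))
  set.seed(4)
  labs <- sample(c("a", "b", "c"), 15, replace = TRUE)
  H <- hatMatrix(labs)
  expect_equal(sum(diag(H)), 3, tolerance = 1e-12)
  expect_equal(H %*% H, H, tolerance = 1e-10)
  expect_equal(H, t(H), tolerance = 1e-12)
  ## explicit X (X'X)^-1 X' for the one-hot design
  X <- model.matrix(~ 0 + factor(labs))
  expect_equal(H, unname(X %*% solve(crossprod(X)) %*% t(X)),
    tolerance = 1e-10)
})

test_that("single-feature euclidean pseudo-F equals classical ANOVA F", {
  set.seed(5)
  y <- rnorm(24) + rep(c(0, 0.8, 1.4), each = 8)
  labs <- rep(c("a", "b", "c"), each = 8)
  d <- featureDist(matrix(y, ncol = 1), "euclidean")
  f <- pseudoF(gowerCenter(d), hatMatrix(labs))
  fAov <- summary(aov(y ~ factor(labs)))[[1]]$`F value`[1]
  expect_equal(f$statistic, fAov, tolerance = 1e-10)
  ## and the fast group-sum path gives the same statistic
  r <- permanovaTest(d, labs, nPermutations = 19, seed = 1)
  expect_equal(r@pseudoF, fAov, tolerance = 1e-10)
})

test_that("trace path and group-sum path agree on random inputs", {
  set.seed(6)
  for (rep in 1:4) {
    n <- sample(10:25, 1)
    k <- sample(2:4, 1)
    y <- matrix(rnorm(n * 5), n, 5)
    labs <- rep(paste0("g", seq_len(k)), length.out = n)
    d <- featureDist(y, sample(c("euclidean", "chord", "gower"), 1))
    tr <- pseudoF(gowerCenter(d), hatMatrix(labs))
    gs <- permanovaTest(d, labs, nPermutations = 1, seed = 1)
    expect_equal(gs@pseudoF, tr$statistic, tolerance = 1e-8)
    expect_equal(gs@ssB, tr$ssB, tolerance = 1e-8)
    expect_equal(gs@ssR, tr$ssR, tolerance = 1e-8)
    ## conservation: SS_B + SS_R = SS_T = tr(G)
    expect_equal(gs@ssB + gs@ssR, sum(diag(gowerCenter(d))),
      tolerance = 1e-8)
  }
})

test_that("F is larger when labels match the block structure", {
  set.seed(7)
  y <- rbind(matrix(rnorm(40), 8, 5), matrix(rnorm(40) + 3, 8, 5))
  d <- featureDist(y, "euclidean")
  matched <- rep(c("a", "b"), each = 8)
  shuffled <- sample(matched)
  fm <- permanovaTest(d, matched, nPermutations = 1, seed = 1)@pseudoF
  fs <- permanovaTest(d, shuffled, nPermutations = 1, seed = 1)@pseudoF
  expect_gt(fm, fs)
})

test_that("permutation p matches exhaustive enumeration at n = 8", {
  set.seed(8)
  y <- matrix(rnorm(16), 8, 2) + rep(c(0, 1.2), each = 4)
  labs <- rep(c("a", "b"), each = 4)
  d <- featureDist(y, "euclidean")
  pExact <- oracleExactPermanovaP(d, labs)
  r <- permanovaTest(d, labs, nPermutations = 4000, seed = 9)
  ## Monte-Carlo error of the permutation estimate at B = 4000
  se <- sqrt(pExact * (1 - pExact) / 4000)
  expect_lt(abs(r@pValue - pExact), 4 * se + 2 / 4001)
})

test_that("p-value support and add-one convention", {
  be <- makeToyExperiment(n = 10, seed = 10)
  r <- permanovaTest(featureDist(be, "euclidean"), batchLabels(be),
    nPermutations = 1, seed = 2)
  expect_true(r@pValue %in% c(0.5, 1))
  r2 <- permanovaTest(featureDist(be, "euclidean"), batchLabels(be),
    nPermutations = 199, seed = 2)
  expect_gte(r2@pValue, 1 / 200)
})

test_that("statistic is invariant under consistent sample reordering", {
  be <- makeToyExperiment(n = 14, seed = 11)
  d <- as.matrix(featureDist(be, "euclidean"))
  labs <- as.character(batchLabels(be))
  perm <- sample(14)
  f1 <- permanovaTest(d, labs, nPermutations = 1, seed = 1)@pseudoF
  f2 <- permanovaTest(d[perm, perm], labs[perm], nPermutations = 1,
    seed = 1)@pseudoF
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("observed F agrees with the vegan reference implementation", {
  be <- simulateBatchData(40, seed = 12)
  d <- featureDist(be, "clark")
  r <- permanovaTest(d, batchLabels(be), nPermutations = 99, seed = 1)
  ref <- vegan::adonis2(as.matrix(d) ~ b,
    data = data.frame(b = batchLabels(be)), permutations = 99)
  expect_equal(r@pseudoF, ref$F[1], tolerance = 1e-8)
})

test_that("identical results from the same seed", {
  be <- makeToyExperiment(n = 30, seed = 13)
  d <- featureDist(be, "euclidean")
  r1 <- permanovaTest(d, batchLabels(be), nPermutations = 99, seed = 3)
  r2 <- permanovaTest(d, batchLabels(be), nPermutations = 99, seed = 3)
  expect_identical(r1@pValue, r2@pValue)
})
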