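## Shared fixtures and independent oracles. The oracles are deliberately
## naive (explicit per-pair / per-element loops) and share no code with the
## package's computational paths.

makeToyExperiment <- function(n = 20, m = 4, k = 2, seed = 42,
                              batch = NULL) {
  set.seed(seed)
  y <- matrix(rnorm(n * m), n, m,
    dimnames = list(paste0("s", seq_len(n)), paste0("f", seq_len(m))))
  b <- batch %||% rep(paste0("b", seq_len(k)), length.out = n)
  batcheval::BatchExperiment(y, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- scalar-loop distance oracles ---------------------------------------

oracleDistPair <- function(x, y, metric, fullData) {
  m <- length(x)
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    chord = {
      xs <- x / sqrt(sum(x^2)); ys <- y / sqrt(sum(y^2))
      sqrt(sum((xs - ys)^2))
    },
    clark = {
      s <- 0; mp <- 0
      for (j in seq_len(m)) {
        if (x[j] + y[j] > 0) {
          mp <- mp + 1
          s <- s + ((x[j] - y[j]) / (x[j] + y[j]))^2
        }
      }
      sqrt(s / mp)
    },
    gower = {
      s <- 0; mp <- 0
      for (j in seq_len(m)) {
        r <- max(fullData[, j]) - min(fullData[, j])
        if (r > 0) { mp <- mp + 1; s <- s + abs(x[j] - y[j]) / r }
      }
      if (mp == 0) 0 else s / mp
    },
    jaccard = {
      b <- sum(abs(x - y)) / sum(x + y)
      2 * b / (1 + b)
    },
    mahalanobis = {
      s <- solve(cov(fullData))
      sqrt(drop(t(x - y) %*% s %*% (x - y)))
    })
}

oracleDistMatrix <- function(data, metric) {
  n <- nrow(data)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j)
      out[i, j] <- oracleDistPair(data[i, ], data[j, ], metric, data)
  out
}

## --- exhaustive PERMANOVA p-value for two groups ------------------------
## Enumerates every assignment of the n samples to groups of the observed
## sizes and computes the exact tail probability of the pseudo-F.

oracleExactPermanovaP <- function(D, labels) {
  d2 <- as.matrix(D)^2
  g <- as.factor(labels)
  n <- nrow(d2)
  n1 <- sum(g == levels(g)[1L])
  sst <- sum(d2) / (2 * n)
  fOf <- function(idx1) {
    idx2 <- setdiff(seq_len(n), idx1)
    ssw <- sum(d2[idx1, idx1]) / (2 * length(idx1)) +
      sum(d2[idx2, idx2]) / (2 * length(idx2))
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  fObs <- fOf(which(g == levels(g)[1L]))
  combos <- utils::combn(n, n1)
  fAll <- apply(combos, 2L, fOf)
  mean(fAll >= fObs - 1e-12)
}

## --- exact Wilcoxon rank-sum p by enumeration ---------------------------

oracleExactWrsP <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1); n <- length(pooled)
  ranks <- rank(pooled)
  wObs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  wAll <- apply(combos, 2L, function(idx)
    sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  ew <- mean(wAll)
  mean(abs(wAll - ew) >= abs(wObs - ew) - 1e-12)
}

## --- brute-force ECDF sweep KS statistic --------------------------------

oracleKsStat <- function(x1, x2) {
  pts <- sort(unique(c(x1, x2)))
  mx <- 0
  for (t in pts) {
    e1 <- mean(x1 <= t); e2 <- mean(x2 <= t)
    mx <- max(mx, abs(e1 - e2))
  }
  mx
}
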