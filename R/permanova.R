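#' Gower-center a distance matrix
#'
#' Forms A with entries a_ij = -d_ij^2 / 2 and double-centers it:
#' G = C A C with C = I - (1/n) 11'. G is symmetric with zero row and
#' column sums; its trace is the total sum of squared distances divided by
#' n, which is what lets PERMANOVA partition distance variation by group.
#'
#' @param D a [DistanceMatrix-class] or symmetric numeric matrix.
#' @return An n-by-n numeric matrix.
#' @examples
#' d <- featureDist(matrix(rnorm(20), 5, 4), "euclidean")
#' rowSums(gowerCenter(d)) # ~ 0
#' @export
gowerCenter <- function(D) {
  d <- if (methods::is(D, "DistanceMatrix")) D@values else as.matrix(D)
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  cm_ <- colMeans(a)
  a - outer(rm_, rep(1, ncol(a))) - outer(rep(1, nrow(a)), cm_) + mean(a)
}

#' Hat (projection) matrix of a one-way group design
#'
#' For the one-hot n-by-g design X of group indicators,
#' H = X (X'X)^{-1} X' reduces to the closed form H_ij = 1/n_k when samples
#' i and j share group k and 0 otherwise; built directly from that block
#' expression. H is symmetric, idempotent, with trace g.
#'
#' @param labels factor (or coercible) of group labels, every level with at
#'   least one sample.
#' @return An n-by-n projection matrix.
#' @examples
#' sum(diag(hatMatrix(rep(c("a", "b"), 4)))) # = 2 groups
#' @export
hatMatrix <- function(labels) {
  g <- droplevels(as.factor(labels))
  idx <- as.integer(g)
  nk <- tabulate(idx, nlevels(g))
  x <- outer(idx, idx, "==") * (1 / nk)[idx]
  x
}

#' Pseudo-F statistic from trace formulas
#'
#' Computes the between-group and residual sums of squared distances as
#' SS_B = tr(H G H) and SS_R = tr((I-H) G (I-H)) and the pseudo-F
#' F = (SS_B / (g-1)) / (SS_R / (n-g)). This literal trace path serves as
#' the reference formulation; [permanovaTest()] uses the algebraically
#' identical group-sum identity for speed and the two are tested to agree.
#'
#' @param G Gower-centered matrix from [gowerCenter()].
#' @param H projection matrix from [hatMatrix()].
#' @param nGroups number of groups g (defaults to `round(sum(diag(H)))`,
#'   the rank of the projection).
#' @return A list with `statistic`, `ssB`, `ssR`. If SS_R is zero (all
#'   within-group distances zero) the statistic is `Inf` with a warning.
#' @export
pseudoF <- function(G, H, nGroups = NULL) {
  n <- nrow(G)
  g <- nGroups %||% round(sum(diag(H)))
  if (n <= g || g < 2)
    bevalStop("need n > g >= 2", class = "batcheval_validation")
  hgh <- H %*% G %*% H
  ihg <- (diag(n) - H) %*% G %*% (diag(n) - H)
  ssB <- sum(diag(hgh))
  ssR <- sum(diag(ihg))
  f <- if (ssR <= 1e-12 * max(1, abs(ssB))) {
    warning("residual sum of squares is zero; pseudo-F is infinite")
    Inf
  } else (ssB / (g - 1)) / (ssR / (n - g))
  list(statistic = f, ssB = ssB, ssR = ssR)
}

## Group-sum identity: SS_T = sum_{i<j} d_ij^2 / n,
## SS_W = sum_k (1/n_k) sum_{i<j in k} d_ij^2, SS_B = SS_T - SS_W.
## sswFromD2 takes the squared-distance matrix and an integer label vector.
sswFromD2 <- function(D2, idx, nk) {
  s <- 0
  for (k in seq_along(nk)) {
    sel <- idx == k
    s <- s + sum(D2[sel, sel]) / (2 * nk[k])
  }
  s
}

#' Distance-based permutation test for a batch effect (PERMANOVA)
#'
#' Tests the association between batch membership and a feature matrix via
#' the pseudo-F statistic on a dissimilarity matrix, with a null
#' distribution obtained by uniformly random relabelings of the samples
#' (equivalently, simultaneous row/column permutations of D). The p-value
#' uses the add-one convention p = (1 + #\{F_b >= F_obs\}) / (1 + B), so it
#' is never exactly zero and is floored at 1/(B+1).
#'
#' Permutation statistics are computed through the group-sum identity
#' (within-group sums of squared distances), evaluated for whole blocks of
#' permutations with dense matrix products; for two groups only one
#' indicator product per block is needed. This keeps runs at thousands of
#' samples and permutations tractable; the trace formulation
#' ([pseudoF()]) is retained as a cross-check.
#'
#' @param D a [DistanceMatrix-class] (or symmetric matrix).
#' @param labels batch labels (factor or coercible), >= 2 levels.
#' @param nPermutations number of random relabelings (default 2000).
#' @param seed optional integer seed for the permutation stream.
#' @return A [PermanovaResult-class].
#' @examples
#' be <- simulateBatchData(60, seed = 4)
#' permanovaTest(featureDist(be, "euclidean"), batchLabels(be),
#'   nPermutations = 199, seed = 1)
#' @export
permanovaTest <- function(D, labels, nPermutations = 2000L, seed = NULL) {
  metric <- if (methods::is(D, "DistanceMatrix")) D@metric else "custom"
  d <- if (methods::is(D, "DistanceMatrix")) D@values else as.matrix(D)
  gfac <- droplevels(as.factor(labels))
  n <- nrow(d)
  if (length(gfac) != n)
    bevalStop("labels do not match the distance matrix",
      class = "batcheval_alignment")
  g <- nlevels(gfac)
  if (g < 2L)
    bevalStop("need >= 2 batch levels", class = "batcheval_validation")
  if (nPermutations < 1L)
    bevalStop("nPermutations must be >= 1", class = "batcheval_validation")
  idx <- as.integer(gfac)
  nk <- tabulate(idx, g)
  D2 <- d^2
  sst <- sum(D2) / (2 * n)
  ssw <- sswFromD2(D2, idx, nk)
  ssb <- sst - ssw
  degenerate <- ssw <= 1e-12 * max(1, sst)
  fObs <- if (degenerate) {
    warning("all within-group distances are zero; pseudo-F is infinite")
    Inf
  } else (ssb / (g - 1)) / (ssw / (n - g))

  fPerm <- withSeed(seed,
    permutePseudoF(D2, idx, nk, n, g, sst, nPermutations))
  ## a random relabeling can reproduce the observed partition exactly, and
  ## the blocked permutation arithmetic orders sums differently, so exact
  ## ties need an epsilon (same convention as vegan's adonis2)
  tol <- sqrt(.Machine$double.eps) * (abs(fObs) + 1)
  p <- (1 + sum(fPerm >= fObs - tol)) / (1 + nPermutations)
  methods::new("PermanovaResult",
    pseudoF = fObs, pValue = p, ssB = ssb, ssR = ssw,
    nPermutations = as.integer(nPermutations), metric = metric,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    nSamples = as.integer(n), nGroups = as.integer(g))
}

## Null pseudo-F values for B random relabelings, evaluated in blocks.
## For each block the within-group squared-distance sums are quadratic
## forms v' D2 v of 0/1 indicator columns, batched into one dense product.
permutePseudoF <- function(D2, idx, nk, n, g, sst, B, blockSize = 64L) {
  fvals <- numeric(B)
  done <- 0L
  ts_ <- sum(D2)
  rs <- rowSums(D2)
  while (done < B) {
    b <- min(blockSize, B - done)
    P <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
    L <- matrix(idx[P], n, b) # permuted labels
    if (g == 2L) {
      V <- (L == 1L) * 1
      s1 <- colSums(V * (D2 %*% V)) # quadratic forms v' D2 v per column
      t1 <- as.vector(crossprod(V, rs))
      s2 <- ts_ - 2 * t1 + s1
      ssw <- s1 / (2 * nk[1L]) + s2 / (2 * nk[2L])
    } else {
      ssw <- numeric(b)
      for (k in seq_len(g)) {
        V <- (L == k) * 1
        ssw <- ssw + colSums(V * (D2 %*% V)) / (2 * nk[k])
      }
    }
    fvals[done + seq_len(b)] <-
      ((sst - ssw) / (g - 1)) / (ssw / (n - g))
    done <- done + b
  }
  fvals
}

setMethod("show", "PermanovaResult", function(object) {
  cat("PERMANOVA (", object@metric, " distance)\n", sep = "")
  cat(sprintf("pseudo-F = %.4g  p = %.4g  (%d permutations)\n",
    object@pseudoF, object@pValue, object@nPermutations))
  cat(sprintf("SS_between = %.4g  SS_within = %.4g  n = %d  groups = %d\n",
    object@ssB, object@ssR, object@nSamples, object@nGroups))
  invisible(NULL)
})
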