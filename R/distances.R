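BEV_METRICS <- c("euclidean", "chord", "clark", "gower", "jaccard",
  "mahalanobis")

## Metrics whose formulas require strictly positive entries.
POSITIVE_METRICS <- c("clark", "jaccard")

#' Elementwise exponential transform of a feature matrix
#'
#' Maps every entry x to e^x, making all values strictly positive. Applied
#' before the Clark and Jaccard (quantitative, Bray-Curtis-based)
#' dissimilarities, whose formulas require positive data. Real-valued
#' radiomic features are typically standardized or signed, so this transform
#' is the canonical way to move them onto the positive half-line without
#' reordering values.
#'
#' @param x a [BatchExperiment-class] or a numeric samples-by-features
#'   matrix.
#' @return An object of the same type with `exp()` applied elementwise.
#' @details Entries with absolute value above 700 would overflow (or
#'   denormalize) in double precision; these raise an error naming the
#'   offending feature rather than propagating `Inf`.
#' @examples
#' expTransform(matrix(c(0, log(2)), 1, 2, dimnames = list("s1", c("a", "b"))))
#' @export
expTransform <- function(x) {
  if (methods::is(x, "BatchExperiment")) {
    a <- SummarizedExperiment::assay(x, "features")
    bad <- abs(a) > 700
    if (any(bad)) {
      feats <- unique(rownames(a)[which(bad, arr.ind = TRUE)[, 1L]])
      bevalStop("exponential transform would overflow for feature(s): ",
        paste(feats, collapse = ", "), class = "batcheval_domain")
    }
    SummarizedExperiment::assay(x, "features") <- exp(a)
    return(x)
  }
  if (any(abs(x) > 700)) {
    j <- unique(which(abs(x) > 700, arr.ind = TRUE)[, 2L])
    nm <- if (!is.null(colnames(x))) colnames(x)[j] else as.character(j)
    bevalStop("exponential transform would overflow for feature(s): ",
      paste(nm, collapse = ", "), class = "batcheval_domain")
  }
  exp(x)
}

#' Pairwise sample dissimilarities for PERMANOVA
#'
#' Computes one of six dissimilarity metrics between all sample pairs of a
#' feature matrix: \code{euclidean}, \code{chord} (Euclidean on L2-normalized
#' rows), \code{clark} (divergence, normalized by the number of informative
#' columns), \code{gower} (range-scaled Manhattan averaged over columns with
#' positive range), \code{jaccard} (the quantitative form `2B/(1+B)` of the
#' Bray-Curtis dissimilarity `B`), and \code{mahalanobis} (Euclidean in the
#' space whitened by the sample feature covariance).
#'
#' The first five are delegated to [vegan::vegdist()]; Mahalanobis is
#' computed by Cholesky whitening so that a singular feature covariance is
#' reported as an explicit error (near-zero covariance entries in highly
#' collinear feature sets make the matrix non-invertible), optionally
#' avoidable with a small ridge term.
#'
#' @param x a [BatchExperiment-class] or numeric samples-by-features matrix.
#' @param metric one of `"euclidean"`, `"chord"`, `"clark"`, `"gower"`,
#'   `"jaccard"`, `"mahalanobis"`.
#' @param transform when to apply [expTransform()] first: `"required"`
#'   (default; only for clark/jaccard, which need positive data), `"all"`,
#'   or `"none"`.
#' @param clarkNormalize logical; divide the Clark sum by the number of
#'   informative columns (default). `FALSE` gives the unnormalized
#'   square-root-of-sums form found in some references.
#' @param ridge non-negative scalar; for Mahalanobis, a ridge
#'   `ridge * mean(diag(S))` added to the covariance. Default 0 (off), so a
#'   singular covariance errors rather than being silently regularized.
#' @return A [DistanceMatrix-class].
#' @examples
#' y <- matrix(rnorm(40), 10, 4)
#' d <- featureDist(y, "euclidean")
#' as.matrix(d)[1:3, 1:3]
#' @export
featureDist <- function(x, metric = BEV_METRICS,
                        transform = c("required", "all", "none"),
                        clarkNormalize = TRUE, ridge = 0) {
  metric <- match.arg(metric)
  transform <- match.arg(transform)
  y <- if (methods::is(x, "BatchExperiment")) featureValues(x) else as.matrix(x)
  if (anyNA(y) || any(!is.finite(y)))
    bevalStop("feature values must be finite", class = "batcheval_validation")
  if (transform == "all" ||
      (transform == "required" && metric %in% POSITIVE_METRICS))
    y <- expTransform(y)
  if (metric %in% POSITIVE_METRICS && any(y <= 0))
    bevalStop(metric, " distance requires strictly positive values; ",
      "apply the exponential transform first", class = "batcheval_domain")
  dm <- switch(metric,
    mahalanobis = mahalanobisDist(y, ridge = ridge),
    gower = gowerDist(y),
    clark = {
      d <- distToMatrix(vegan::vegdist(y, method = "clark"))
      if (!clarkNormalize) d <- d * sqrt(ncol(y))
      d
    },
    distToMatrix(vegan::vegdist(y, method = metric))
  )
  diag(dm) <- 0
  dimnames(dm) <- list(rownames(y), rownames(y))
  methods::new("DistanceMatrix", values = dm, metric = metric)
}

## Fast symmetric expansion of a stats::dist vector (as.matrix.dist is
## noticeably slower at thousands of samples).
distToMatrix <- function(d) {
  n <- attr(d, "Size")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- as.vector(d)
  m + t(m)
}

## Range-scaled Gower dissimilarity; columns with zero range carry no
## information about sample differences and are dropped from the average
## rather than contributing zeros to the denominator.
gowerDist <- function(y) {
  rng <- apply(y, 2L, function(col) diff(range(col)))
  keep <- rng > 0
  if (!any(keep)) return(matrix(0, nrow(y), nrow(y)))
  distToMatrix(vegan::vegdist(y[, keep, drop = FALSE], method = "gower"))
}

## Classical Mahalanobis via Cholesky whitening of the sample covariance.
mahalanobisDist <- function(y, ridge = 0) {
  S <- stats::cov(y)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), ncol(S))
  ch <- tryCatch(chol(S), error = function(e)
    bevalStop("singular covariance: the feature covariance matrix is not ",
      "invertible (near-zero or collinear features)",
      class = "batcheval_singular"))
  z <- t(backsolve(ch, t(y), transpose = TRUE))
  distToMatrix(stats::dist(z))
}

#' @describeIn featureDist the metric tag of a DistanceMatrix.
#' @export
setMethod("metricName", "DistanceMatrix", function(x) x@metric)

#' Coerce a DistanceMatrix to a base matrix
#'
#' @param x a [DistanceMatrix-class].
#' @param ... ignored.
#' @return The underlying symmetric numeric matrix.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix (", object@metric, "): ", nrow(object@values),
    " samples\n", sep = "")
  invisible(NULL)
})
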