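#' Construct a BatchExperiment
#'
#' Assembles a sample-by-feature matrix, batch labels, and optional covariate
#' columns into a validated [BatchExperiment-class] container.
#'
#' @param features numeric matrix or data.frame, n samples by m features.
#'   Row names (or `sampleIds`) identify samples; column names (or
#'   `featureNames`) identify features.
#' @param batch factor or character vector of length n giving each sample's
#'   batch membership.
#' @param covariates optional data.frame (n rows) of covariate columns to
#'   protect during harmonization; numeric or factor, no missing values.
#' @param referenceLevel the batch level used as the model intercept for
#'   effect-size estimation; defaults to the first level in sorted order.
#' @param sampleIds,featureNames optional explicit identifiers, overriding
#'   the dimnames of `features`.
#' @return A validated `BatchExperiment`.
#' @examples
#' y <- matrix(rnorm(40), 10, 4)
#' be <- BatchExperiment(y, rep(c("a", "b"), each = 5))
#' batchLabels(be)
#' @export
BatchExperiment <- function(features, batch, covariates = NULL,
                            referenceLevel = NULL,
                            sampleIds = NULL, featureNames = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features))
    bevalStop("features must be a matrix or data.frame",
      class = "batcheval_validation")
  n <- nrow(features); m <- ncol(features)
  sampleIds <- sampleIds %||% rownames(features) %||%
    sprintf("sample%0*d", nchar(n), seq_len(n))
  featureNames <- featureNames %||% colnames(features) %||%
    sprintf("feature%0*d", nchar(m), seq_len(m))
  if (length(batch) != n)
    bevalStop("batch labels (", length(batch),
      ") do not match the sample count (", n, ")",
      class = "batcheval_alignment")
  batch <- if (is.factor(batch)) droplevels(batch)
    else factor(batch, levels = sort(unique(as.character(batch))))
  referenceLevel <- referenceLevel %||% sort(levels(batch))[1L]
  if (!referenceLevel %in% levels(batch))
    bevalStop("referenceLevel '", referenceLevel,
      "' is not a batch level", class = "batcheval_validation")
  batch <- stats::relevel(batch, ref = referenceLevel)
  cd <- S4Vectors::DataFrame(batch = batch, row.names = sampleIds)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      bevalStop("covariate rows do not match the sample count",
        class = "batcheval_alignment")
    if ("batch" %in% colnames(covariates))
      bevalStop("'batch' is a reserved column name",
        class = "batcheval_validation")
    for (cn in colnames(covariates)) cd[[cn]] <- covariates[[cn]]
  }
  a <- t(features)
  dimnames(a) <- list(featureNames, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = a), colData = cd,
    metadata = list(batchVar = "batch",
      referenceLevel = referenceLevel))
  obj <- methods::new("BatchExperiment", se)
  methods::validObject(obj)
  obj
}

#' Batch labels of a BatchExperiment
#'
#' Returns the per-sample batch factor, releveled so the reference level is
#' the first (intercept) level.
#'
#' @param x a [BatchExperiment-class].
#' @return A factor of length `n`.
#' @export
setMethod("batchLabels", "BatchExperiment", function(x) {
  SummarizedExperiment::colData(x)[[S4Vectors::metadata(x)$batchVar]]
})

#' Reference batch level
#'
#' The batch level used as the linear-model intercept when quantifying
#' per-batch effect sizes. Assigning a new value relevels the stored factor.
#'
#' @param x a [BatchExperiment-class].
#' @param value a batch level name.
#' @return The reference level string; the setter returns the updated object.
#' @export
setMethod("referenceLevel", "BatchExperiment", function(x)
  S4Vectors::metadata(x)$referenceLevel)

#' @rdname referenceLevel
#' @export
setReplaceMethod("referenceLevel", "BatchExperiment", function(x, value) {
  b <- batchLabels(x)
  if (!value %in% levels(b))
    bevalStop("'", value, "' is not a batch level",
      class = "batcheval_validation")
  SummarizedExperiment::colData(x)[[S4Vectors::metadata(x)$batchVar]] <-
    stats::relevel(b, ref = value)
  S4Vectors::metadata(x)$referenceLevel <- value
  methods::validObject(x)
  x
})

#' Feature values as a sample-by-feature matrix
#'
#' @param x a [BatchExperiment-class].
#' @return An n-by-m numeric matrix (samples in rows), the user-facing
#'   orientation of the stored assay.
#' @export
setMethod("featureValues", "BatchExperiment", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' Covariate columns of a BatchExperiment
#'
#' @param x a [BatchExperiment-class].
#' @return A data.frame of the non-batch colData columns (zero columns if
#'   none were supplied).
#' @export
setMethod("covariateTable", "BatchExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  keep <- setdiff(colnames(cd), S4Vectors::metadata(x)$batchVar)
  as.data.frame(cd[, keep, drop = FALSE])
})

setMethod("show", "BatchExperiment", function(object) {
  b <- batchLabels(object)
  cat("BatchExperiment:", ncol(object), "samples x", nrow(object),
    "features\n")
  cat("batch levels (", nlevels(b), "): ",
    paste(utils::head(levels(b), 6), collapse = ", "),
    if (nlevels(b) > 6) ", ..." else "", "\n", sep = "")
  cat("reference level:", referenceLevel(object), "\n")
  cv <- covariateTable(object)
  if (ncol(cv))
    cat("covariates:", paste(colnames(cv), collapse = ", "), "\n")
  md <- S4Vectors::metadata(object)
  if (!is.null(md$truth))
    cat("simulated; batch effects present:", md$truth, "\n")
  invisible(NULL)
})

## Convenience used throughout: n samples / m features in user orientation.
nSamples <- function(x) ncol(SummarizedExperiment::assay(x))
nFeatures <- function(x) nrow(SummarizedExperiment::assay(x))
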