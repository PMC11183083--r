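#' BatchExperiment: a feature matrix with batch annotation
#'
#' `BatchExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] to carry an n-sample by
#' m-feature real-valued table (stored feature-by-sample in the assay, as is
#' conventional) together with a categorical batch label per sample and
#' optional covariate columns in `colData`. The batch column name and the
#' designated reference batch level are kept in `metadata()`.
#'
#' Validity requires: at least 2 samples and 1 feature; finite, non-missing
#' assay values; unique sample and feature names; every batch level with at
#' least 2 samples; and a reference level that is one of the batch levels.
#' A single batch level is tolerated by the container (harmonization treats
#' it as a no-op) but the statistical tests require at least two.
#'
#' @seealso [BatchExperiment()] for construction, [batchLabels()],
#'   [featureValues()], [referenceLevel()].
#' @aliases BatchExperiment-class
#' @exportClass BatchExperiment
setClass("BatchExperiment", contains = "SummarizedExperiment")

#' DistanceMatrix: pairwise sample dissimilarities tagged with their metric
#'
#' A symmetric n-by-n matrix of non-negative dissimilarities with zero
#' diagonal, produced by [featureDist()]. The metric name is carried so that
#' downstream results can report it.
#'
#' @aliases DistanceMatrix-class
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(values = "matrix", metric = "character"))

#' PermanovaResult: outcome of a distance-based permutation test
#'
#' Holds the observed pseudo-F statistic, the permutation p-value, the
#' between- and within-group sums of squared distances, the permutation
#' count, the distance metric, and the RNG seed used (NA if none was set).
#'
#' @aliases PermanovaResult-class
#' @exportClass PermanovaResult
setClass("PermanovaResult",
  representation(pseudoF = "numeric", pValue = "numeric",
    ssB = "numeric", ssR = "numeric", nPermutations = "integer",
    metric = "character", seed = "integer",
    nSamples = "integer", nGroups = "integer"))

#' ResiResult: robust effect size of batch for one feature
#'
#' Per-coefficient signed robust effect size index values (one per
#' non-reference batch level) with percentile-bootstrap confidence bounds,
#' plus the non-negative overall index for the joint batch effect.
#'
#' @aliases ResiResult-class
#' @exportClass ResiResult
setClass("ResiResult",
  representation(coefficients = "data.frame", overall = "numeric",
    overallCi = "numeric", nBoot = "integer",
    referenceLevel = "character", level = "numeric"))

#' CombatModel: fitted empirical-Bayes location/scale harmonization
#'
#' Per-feature grand mean and covariate coefficients, pooled variance, and
#' per-(batch, feature) EB-shrunken location (`gammaStar`) and scale
#' (`deltaStar`, a variance) estimates. Constant features are flagged and
#' bypass adjustment. A model fitted on a single batch level is an identity
#' transform.
#'
#' @aliases CombatModel-class
#' @exportClass CombatModel
setClass("CombatModel",
  representation(batchLevels = "character", nPerBatch = "integer",
    gammaStar = "matrix", deltaStar = "matrix",
    varPooled = "numeric", grandMean = "numeric",
    covCoef = "matrix", covariateNames = "character",
    covLevels = "list", featureNames = "character",
    constantFeatures = "logical", identity = "logical"))

#' PowerSummary: aggregated results of a power/Type-I-error study
#'
#' Rejection rates with Monte-Carlo standard errors for the dataset-level
#' PERMANOVA (per metric) and the feature-level univariate tests (per test),
#' in both the with-batch and null arms, plus robust effect size summaries
#' (mean absolute point estimate and mean CI width) per arm and sample size.
#'
#' @aliases PowerSummary-class
#' @exportClass PowerSummary
setClass("PowerSummary",
  representation(permanova = "data.frame", univariate = "data.frame",
    resi = "data.frame", config = "list"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v))
    return("values must be a square numeric matrix")
  if (any(!is.finite(v))) return("distances must be finite")
  if (any(v < -1e-12)) return("distances must be non-negative")
  if (max(abs(diag(v))) > 1e-10) return("diagonal must be zero")
  if (max(abs(v - t(v))) > 1e-8 * (1 + max(abs(v))))
    return("distance matrix must be symmetric")
  if (length(object@metric) != 1L) return("metric must be a single string")
  TRUE
})

setValidity("PermanovaResult", function(object) {
  if (object@pValue <= 0 || object@pValue > 1)
    return("p-value must lie in (0, 1]")
  if (object@pValue < 1 / (object@nPermutations + 1) - 1e-12)
    return("p-value below the add-one permutation floor")
  ## semimetric dissimilarities (e.g. Gower, Bray-Curtis-based) give a
  ## non-PSD centered matrix, so small negative components are legitimate
  if (!all(is.finite(c(object@ssB, object@ssR))))
    return("sums of squares must be finite")
  TRUE
})

setValidity("BatchExperiment", function(object) {
  md <- S4Vectors::metadata(object)
  bv <- md$batchVar
  if (is.null(bv) || !bv %in% colnames(SummarizedExperiment::colData(object)))
    return("metadata()$batchVar must name a colData column")
  a <- SummarizedExperiment::assay(object)
  if (ncol(a) < 2L) return("at least 2 samples are required")
  if (nrow(a) < 1L) return("at least 1 feature is required")
  if (!is.numeric(a)) return("feature values must be numeric")
  if (anyNA(a) || any(!is.finite(a)))
    return("feature values must be finite and non-missing")
  if (is.null(colnames(a)) || anyDuplicated(colnames(a)))
    return("sample ids must be present and unique")
  if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
    return("feature names must be present and unique")
  b <- SummarizedExperiment::colData(object)[[bv]]
  if (!is.factor(b)) return("batch labels must be a factor")
  tab <- table(b)
  if (any(tab < 2L))
    return(paste0("every batch level needs >= 2 samples; offending: ",
      paste(names(tab)[tab < 2L], collapse = ", ")))
  rl <- md$referenceLevel
  if (is.null(rl) || !rl %in% levels(b))
    return("metadata()$referenceLevel must be one of the batch levels")
  cd <- SummarizedExperiment::colData(object)
  if (any(vapply(seq_len(ncol(cd)), function(j) anyNA(cd[[j]]), logical(1))))
    return("colData must not contain missing values")
  TRUE
})
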