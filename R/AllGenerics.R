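#' @rdname batchLabels
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))

#' @rdname referenceLevel
#' @export
setGeneric("referenceLevel", function(x) standardGeneric("referenceLevel"))

#' @rdname referenceLevel
#' @export
setGeneric("referenceLevel<-",
  function(x, value) standardGeneric("referenceLevel<-"))

#' @rdname featureValues
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname covariateTable
#' @export
setGeneric("covariateTable", function(x) standardGeneric("covariateTable"))

#' @rdname featureDist
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' Write a result record to disk
#'
#' Scalar results (PERMANOVA) are written as JSON at full precision,
#' including the RNG seed used; per-feature tables as delimited text.
#' Every writer has a matching reader and round-trips exactly.
#'
#' @param x the result object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
setGeneric("writeResult", function(x, path) standardGeneric("writeResult"))
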