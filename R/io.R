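readDelimAuto <- function(path) {
  if (!file.exists(path))
    bevalStop("file not found: ", path, class = "batcheval_io")
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
    stringsAsFactors = FALSE, comment.char = "", quote = "\"")
}

#' Read a feature table and sample metadata into a BatchExperiment
#'
#' Reads two delimited text files (CSV or TSV, autodetected by extension):
#' a feature table (samples in rows, one sample-ID column, numeric feature
#' columns) and a metadata table containing the batch column and any
#' covariate columns. The two files must describe exactly the same sample
#' set; metadata rows are reindexed to the feature table's row order.
#' Missing values are a hard error - the downstream methods assume complete
#' matrices and no imputation is attempted.
#'
#' @param featuresPath,metadataPath paths to the delimited files.
#' @param batchColumn name of the metadata column holding batch labels.
#' @param covariateColumns metadata columns to carry as covariates
#'   (default none).
#' @param sampleIdColumn the sample-ID column in each file: a name or a
#'   column index (default: the first column).
#' @param referenceLevel optional reference batch level (default: first in
#'   sorted order).
#' @return A validated [BatchExperiment-class] with >= 2 batch levels.
#' @export
readBatchDataset <- function(featuresPath, metadataPath, batchColumn,
                             covariateColumns = character(0),
                             sampleIdColumn = 1L,
                             referenceLevel = NULL) {
  feat <- readDelimAuto(featuresPath)
  meta <- readDelimAuto(metadataPath)
  fid <- resolveIdColumn(feat, sampleIdColumn, featuresPath)
  mid <- resolveIdColumn(meta, sampleIdColumn, metadataPath)
  fids <- as.character(feat[[fid]])
  mids <- as.character(meta[[mid]])
  if (anyDuplicated(fids))
    bevalStop("duplicate sample IDs in ", featuresPath,
      class = "batcheval_alignment")
  if (anyDuplicated(mids))
    bevalStop("duplicate sample IDs in ", metadataPath,
      class = "batcheval_alignment")
  if (!setequal(fids, mids))
    bevalStop("sample ID sets differ between the feature and metadata ",
      "tables", class = "batcheval_alignment")
  meta <- meta[match(fids, mids), , drop = FALSE]
  if (!batchColumn %in% colnames(meta))
    bevalStop("batch column '", batchColumn, "' not present in metadata",
      class = "batcheval_validation")
  missingCov <- setdiff(covariateColumns, colnames(meta))
  if (length(missingCov))
    bevalStop("covariate column(s) not in metadata: ",
      paste(missingCov, collapse = ", "), class = "batcheval_validation")
  vals <- feat[, setdiff(colnames(feat), colnames(feat)[fid]),
    drop = FALSE]
  nonNum <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(nonNum))
    bevalStop("non-numeric feature column(s): ",
      paste(nonNum, collapse = ", "), class = "batcheval_parse")
  y <- as.matrix(vals)
  rownames(y) <- fids
  if (anyNA(y))
    bevalStop("missing values in the feature table; complete matrices ",
      "are required (no imputation)", class = "batcheval_validation")
  batch <- meta[[batchColumn]]
  if (anyNA(batch))
    bevalStop("missing batch labels", class = "batcheval_validation")
  if (length(unique(batch)) < 2L)
    bevalStop("need >= 2 batch levels", class = "batcheval_validation")
  covs <- if (length(covariateColumns))
    meta[, covariateColumns, drop = FALSE] else NULL
  BatchExperiment(y, batch = batch, covariates = covs,
    referenceLevel = referenceLevel, sampleIds = fids)
}

resolveIdColumn <- function(df, col, path) {
  if (is.numeric(col)) {
    if (col < 1 || col > ncol(df))
      bevalStop("sample-ID column index out of range in ", path,
        class = "batcheval_validation")
    return(as.integer(col))
  }
  j <- match(col, colnames(df))
  if (is.na(j))
    bevalStop("sample-ID column '", col, "' not found in ", path,
      class = "batcheval_validation")
  j
}

## Full round-trip precision: 17 significant digits survive text -> double.
fmtFull <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a BatchExperiment as a feature/metadata CSV pair
#'
#' Feature values are written as decimal text with 17 significant digits,
#' so writing and re-reading reproduces the doubles bit-for-bit.
#'
#' @param x a [BatchExperiment-class].
#' @param featuresPath,metadataPath output CSV paths.
#' @return The two paths, invisibly.
#' @export
writeBatchDataset <- function(x, featuresPath, metadataPath) {
  y <- featureValues(x)
  df <- data.frame(sample_id = rownames(y), check.names = FALSE)
  for (j in seq_len(ncol(y))) df[[colnames(y)[j]]] <- fmtFull(y[, j])
  utils::write.table(df, featuresPath, sep = ",", row.names = FALSE,
    quote = FALSE)
  cd <- SummarizedExperiment::colData(x)
  md <- data.frame(sample_id = rownames(cd), check.names = FALSE)
  for (cn in colnames(cd)) {
    v <- cd[[cn]]
    md[[cn]] <- if (is.numeric(v)) fmtFull(v) else as.character(v)
  }
  utils::write.table(md, metadataPath, sep = ",", row.names = FALSE,
    quote = FALSE)
  invisible(c(featuresPath, metadataPath))
}

#' @describeIn writeResult PERMANOVA result as JSON with keys `metric`,
#'   `pseudo_F`, `p_value`, `SS_B`, `SS_R`, `n_permutations`, `seed`.
#' @export
setMethod("writeResult", "PermanovaResult", function(x, path) {
  jsonlite::write_json(list(metric = x@metric, pseudo_F = x@pseudoF,
    p_value = x@pValue, SS_B = x@ssB, SS_R = x@ssR,
    n_permutations = x@nPermutations,
    seed = if (is.na(x@seed)) NULL else x@seed,
    n_samples = x@nSamples, n_groups = x@nGroups),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
})

#' Read a PERMANOVA result written by [writeResult()]
#'
#' @param path JSON path.
#' @return A [PermanovaResult-class].
#' @export
readPermanovaResult <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("PermanovaResult", pseudoF = j$pseudo_F,
    pValue = j$p_value, ssB = j$SS_B, ssR = j$SS_R,
    nPermutations = as.integer(j$n_permutations), metric = j$metric,
    seed = if (is.null(j$seed)) NA_integer_ else as.integer(j$seed),
    nSamples = as.integer(j$n_samples), nGroups = as.integer(j$n_groups))
}

#' @describeIn writeResult a per-feature table (e.g. from [resiTable()] or
#'   [featureTestSuite()]) as CSV at full precision; an empty table is an
#'   error and nothing is written.
#' @export
setMethod("writeResult", "data.frame", function(x, path) {
  if (nrow(x) == 0L)
    bevalStop("refusing to write an empty result table",
      class = "batcheval_validation")
  out <- x
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmtFull(out[[j]])
  utils::write.table(out, path, sep = ",", row.names = FALSE,
    quote = FALSE)
  invisible(path)
})

#' Read a per-feature result table written by [writeResult()]
#'
#' @param path CSV path.
#' @return A data.frame with numeric columns restored.
#' @export
readResultTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) &&
        all(df[[j]] %in% c("TRUE", "FALSE", "NA")))
      df[[j]] <- as.logical(df[[j]])
  }
  df
}
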