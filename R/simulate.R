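#' Simulate a radiomics-style feature matrix with location/scale batch effects
#'
#' Generates `nSamples` x `nFeatures` standard-normal residuals
#' eps ~ N(0, 1), assigns samples uniformly at random to `nGroups` batch
#' groups, and, when `addBatch = TRUE`, injects a batch effect per group i:
#' the residuals are first multiplied by a scale effect
#' delta_i ~ Uniform(deltaRange) and a location effect
#' gamma_i ~ Uniform(gammaRange) is then added, giving
#' Y = gamma_i + delta_i * eps. With `addBatch = FALSE` the data are the raw
#' residuals (mathematically identical to gamma = 0, delta = 1).
#'
#' By default one (gamma_i, delta_i) pair is drawn per group and applied to
#' all features of the dataset; `paramsPerFeature = TRUE` draws an
#' independent pair per (group, feature). Both choices give each feature the
#' same marginal two-group location/scale alternative.
#'
#' @param nSamples number of samples n (at least `2 * nGroups`).
#' @param nFeatures number of features m (default 20).
#' @param nGroups number of batch groups (default 2).
#' @param addBatch logical; inject batch effects (default TRUE).
#' @param gammaRange numeric interval for the location effect
#'   (default `c(-2, 2)`).
#' @param deltaRange strictly positive interval for the scale effect
#'   (default `c(0.8, 1.2)`).
#' @param paramsPerFeature draw independent effects per (group, feature)
#'   instead of sharing one pair per group across features.
#' @param seed optional integer seed; the surrounding RNG stream is left
#'   untouched.
#' @return A [BatchExperiment-class]; `metadata()` carries `truth`
#'   (whether batch effects are present), `simParams` (the drawn gamma and
#'   delta), and the generating configuration.
#' @examples
#' be <- simulateBatchData(100, seed = 1)
#' S4Vectors::metadata(be)$simParams
#' @export
simulateBatchData <- function(nSamples, nFeatures = 20L, nGroups = 2L,
                              addBatch = TRUE,
                              gammaRange = c(-2, 2),
                              deltaRange = c(0.8, 1.2),
                              paramsPerFeature = FALSE, seed = NULL) {
  if (nGroups < 2L)
    bevalStop("nGroups must be >= 2", class = "batcheval_validation")
  if (nSamples < 2L * nGroups)
    bevalStop("nSamples must be >= 2 * nGroups",
      class = "batcheval_validation")
  if (any(deltaRange <= 0))
    bevalStop("deltaRange must be strictly positive",
      class = "batcheval_validation")
  withSeed(seed, {
    g <- drawAssignment(nSamples, nGroups)
    eps <- matrix(stats::rnorm(nSamples * nFeatures), nSamples, nFeatures)
    params <- list(gamma = numeric(0), delta = numeric(0))
    if (addBatch) {
      if (paramsPerFeature) {
        delta <- matrix(stats::runif(nGroups * nFeatures, deltaRange[1L],
          deltaRange[2L]), nGroups, nFeatures)
        y <- eps * delta[g, , drop = FALSE]
        gamma <- matrix(stats::runif(nGroups * nFeatures, gammaRange[1L],
          gammaRange[2L]), nGroups, nFeatures)
        y <- y + gamma[g, , drop = FALSE]
      } else {
        delta <- stats::runif(nGroups, deltaRange[1L], deltaRange[2L])
        y <- eps * delta[g]
        gamma <- stats::runif(nGroups, gammaRange[1L], gammaRange[2L])
        y <- y + gamma[g]
      }
      params <- list(gamma = gamma, delta = delta)
    } else {
      y <- eps
    }
    be <- BatchExperiment(y,
      batch = factor(paste0("batch", g),
        levels = paste0("batch", seq_len(nGroups))),
      sampleIds = sprintf("sample%0*d", nchar(nSamples), seq_len(nSamples)),
      featureNames = sprintf("feature%0*d", nchar(nFeatures),
        seq_len(nFeatures)))
    S4Vectors::metadata(be)$truth <- addBatch
    S4Vectors::metadata(be)$simParams <- params
    S4Vectors::metadata(be)$simConfig <- list(nSamples = nSamples,
      nFeatures = nFeatures, nGroups = nGroups, addBatch = addBatch,
      gammaRange = gammaRange, deltaRange = deltaRange,
      paramsPerFeature = paramsPerFeature, seed = seed)
    be
  })
}

## i.i.d. uniform assignment (unbalanced draws kept); redraw if a group ends
## up with fewer than 2 samples, bounded at 100 attempts.
drawAssignment <- function(n, k, maxTries = 100L) {
  for (i in seq_len(maxTries)) {
    g <- sample.int(k, n, replace = TRUE)
    if (min(tabulate(g, k)) >= 2L) return(g)
  }
  bevalStop("could not assign >= 2 samples to every batch group after ",
    maxTries, " draws", class = "batcheval_validation")
}

#' Simulate an independent sequence of datasets
#'
#' Produces `nIterations` datasets from [simulateBatchData()], iteration k
#' seeded with [iterationSeed]`(baseSeed, k)` so each is reproducible from
#' `(baseSeed, k)` alone.
#'
#' @param nIterations number of datasets.
#' @param nSamples,... forwarded to [simulateBatchData()].
#' @param baseSeed study-level seed.
#' @return A list of [BatchExperiment-class] objects.
#' @examples
#' sims <- simulateStudy(3, nSamples = 50, baseSeed = 1)
#' length(sims)
#' @export
simulateStudy <- function(nIterations, nSamples, ..., baseSeed = 1L) {
  stopifnot(nIterations >= 1L)
  lapply(seq_len(nIterations), function(k)
    simulateBatchData(nSamples, ..., seed = iterationSeed(baseSeed, k)))
}
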