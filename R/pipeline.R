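#' Power and Type-I-error study for batch-effect detection
#'
#' Runs the full simulation experiment: for every sample size and arm
#' (with-batch, null), `nIterations` datasets of `nFeatures` features are
#' generated with [simulateBatchData()]; each dataset receives one
#' PERMANOVA decision per distance metric (dataset-level), one decision per
#' (feature, univariate test) (feature-level), and per-feature robust
#' effect size point estimates (optionally with bootstrap interval widths).
#' Power is the rejection fraction at `alpha` over the with-batch arm and
#' the Type-I error the same fraction over the null arm.
#'
#' Every iteration derives its own seed from `seed` via [iterationSeed()],
#' so the study is reproducible end-to-end and insensitive to execution
#' order. A `scale` factor >= 1 divides the iteration, permutation, and
#' bootstrap counts for quick runs; reported Monte-Carlo standard errors
#' keep scaled runs interpretable.
#'
#' @param sampleSizes sample sizes to study (default `c(100, 1000, 2500)`).
#' @param nIterations simulated datasets per (n, arm) (default 250).
#' @param nFeatures features per dataset (default 20).
#' @param nPermutations PERMANOVA permutations (default 2000).
#' @param nBoot bootstrap replicates per feature for interval widths
#'   (default 500; 0 skips intervals).
#' @param alpha significance level (default 0.05).
#' @param metrics distance metrics to include (default all six).
#' @param tests univariate tests to include (default wrs, ks, ad).
#' @param arms `"batch"`, `"null"`, or both (default both).
#' @param transform exponential-transform mode passed to [featureDist()].
#' @param resi logical; compute effect-size summaries (default TRUE).
#' @param seed study seed (default 1).
#' @param scale integer >= 1 dividing iterations/permutations/bootstraps.
#' @param verbose print per-iteration progress.
#' @return A [PowerSummary-class] with data.frames `permanova`
#'   (n, arm, metric, rate, se, nIter, nFailed), `univariate`
#'   (n, arm, test, rate, se, rateByIter, nTests), and `resi`
#'   (n, arm, meanAbsResi, sdResi, meanCiWidth, nFeatures).
#' @examples
#' ps <- runPowerStudy(sampleSizes = 60, nIterations = 4,
#'   nPermutations = 99, nBoot = 0, metrics = "euclidean", seed = 1)
#' ps@permanova
#' @export
runPowerStudy <- function(sampleSizes = c(100, 1000, 2500),
                          nIterations = 250L, nFeatures = 20L,
                          nPermutations = 2000L, nBoot = 500L,
                          alpha = 0.05, metrics = BEV_METRICS,
                          tests = c("wrs", "ks", "ad"),
                          arms = c("batch", "null"),
                          transform = "required", resi = TRUE,
                          seed = 1L, scale = 1L, verbose = FALSE) {
  metrics <- if (length(metrics))
    match.arg(metrics, BEV_METRICS, several.ok = TRUE)
    else character(0)
  tests <- if (length(tests))
    match.arg(tests, c("wrs", "ks", "ad"), several.ok = TRUE)
    else character(0)
  arms <- match.arg(arms, c("batch", "null"), several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1, scale >= 1)
  nIterations <- max(1L, as.integer(ceiling(nIterations / scale)))
  nPermutations <- max(1L, as.integer(ceiling(nPermutations / scale)))
  nBoot <- as.integer(ceiling(nBoot / scale))

  permRows <- list(); uniRows <- list(); resiRows <- list()
  for (ni in seq_along(sampleSizes)) {
    n <- sampleSizes[ni]
    for (ai in seq_along(arms)) {
      arm <- arms[ai]
      armSeed <- iterationSeed(seed, ni * 1000L + ai)
      permRej <- matrix(NA, nIterations, length(metrics),
        dimnames = list(NULL, metrics))
      uniRej <- array(NA, c(nIterations, nFeatures, length(tests)),
        dimnames = list(NULL, NULL, tests))
      absResi <- matrix(NA_real_, nIterations, nFeatures)
      ciWidth <- matrix(NA_real_, nIterations, nFeatures)
      for (it in seq_len(nIterations)) {
        itSeed <- iterationSeed(armSeed, it)
        be <- simulateBatchData(n, nFeatures = nFeatures,
          addBatch = (arm == "batch"), seed = itSeed)
        labs <- batchLabels(be)
        for (mi in seq_along(metrics)) {
          res <- tryCatch({
            d <- featureDist(be, metrics[mi], transform = transform)
            permanovaTest(d, labs, nPermutations = nPermutations,
              seed = iterationSeed(itSeed, 100L + mi))
          }, error = function(e) NULL)
          if (!is.null(res)) permRej[it, mi] <- res@pValue < alpha
        }
        if (length(tests)) {
          st <- featureTestSuite(be, tests = tests, alpha = alpha)
          for (ti in seq_along(tests))
            uniRej[it, , ti] <- st$reject[st$test == tests[ti]]
        }
        if (resi) {
          rt <- resiTable(be, nBoot = nBoot,
            seed = iterationSeed(itSeed, 500L), engine = "grouped")
          ## two-group design: one row per feature; summarize the overall
          ## (joint batch) index, the calibration surface of the study
          absResi[it, ] <- abs(rt$overall)[seq_len(nFeatures)]
          if (nBoot > 0L)
            ciWidth[it, ] <-
              (rt$overallCiHigh - rt$overallCiLow)[seq_len(nFeatures)]
        }
        if (verbose)
          message(sprintf("n=%d arm=%s iter=%d/%d (seed %d)",
            n, arm, it, nIterations, itSeed))
      }
      for (mi in seq_along(metrics)) {
        ok <- !is.na(permRej[, mi])
        r <- mean(permRej[ok, mi])
        permRows[[length(permRows) + 1L]] <- data.frame(n = n, arm = arm,
          metric = metrics[mi], rate = r,
          se = sqrt(r * (1 - r) / sum(ok)), nIter = sum(ok),
          nFailed = sum(!ok))
      }
      for (ti in seq_along(tests)) {
        rej <- uniRej[, , ti]
        r <- mean(rej, na.rm = TRUE)
        byIter <- rowMeans(rej, na.rm = TRUE)
        uniRows[[length(uniRows) + 1L]] <- data.frame(n = n, arm = arm,
          test = tests[ti], rate = r,
          se = stats::sd(byIter) / sqrt(length(byIter)),
          rateByIter = mean(byIter), nTests = sum(!is.na(rej)))
      }
      if (resi) {
        resiRows[[length(resiRows) + 1L]] <- data.frame(n = n, arm = arm,
          meanAbsResi = mean(absResi, na.rm = TRUE),
          sdResi = stats::sd(as.vector(absResi), na.rm = TRUE),
          meanCiWidth = if (nBoot > 0L) mean(ciWidth, na.rm = TRUE)
            else NA_real_,
          nFeatures = sum(!is.na(absResi)))
      }
    }
  }
  methods::new("PowerSummary",
    permanova = do.call(rbind, permRows) %||% data.frame(),
    univariate = do.call(rbind, uniRows) %||% data.frame(),
    resi = if (resi) do.call(rbind, resiRows) else data.frame(),
    config = list(sampleSizes = sampleSizes, nIterations = nIterations,
      nFeatures = nFeatures, nPermutations = nPermutations,
      nBoot = nBoot, alpha = alpha, metrics = metrics, tests = tests,
      arms = arms, transform = transform, seed = seed, scale = scale))
}

setMethod("show", "PowerSummary", function(object) {
  cfg <- object@config
  cat("Power/Type-I study:", cfg$nIterations, "iterations x",
    cfg$nFeatures, "features;", cfg$nPermutations, "permutations\n\n")
  cat("Dataset-level PERMANOVA rejection rates:\n")
  print(object@permanova, row.names = FALSE, digits = 3)
  cat("\nFeature-level univariate rejection rates:\n")
  print(object@univariate, row.names = FALSE, digits = 3)
  if (nrow(object@resi)) {
    cat("\nRobust effect size summaries:\n")
    print(object@resi, row.names = FALSE, digits = 3)
  }
  invisible(NULL)
})

#' Screen a dataset for batch effects with PERMANOVA over several metrics
#'
#' Runs [permanovaTest()] once per requested metric. A metric that fails
#' (typically Mahalanobis on a singular feature covariance) is reported in
#' the table with its error message instead of aborting the screen; only
#' if every metric fails is an error raised.
#'
#' @param x a [BatchExperiment-class].
#' @param metrics metrics to run (default all six).
#' @param nPermutations permutations per test (default 2000).
#' @param transform exponential-transform mode (see [featureDist()]).
#' @param seed optional seed; metric i uses substream
#'   [iterationSeed]`(seed, i)`.
#' @param alpha significance level for the `reject` column.
#' @return A list with `table` (data.frame: metric, pseudoF, pValue,
#'   reject, status) and `results` (the [PermanovaResult-class] objects,
#'   NULL where failed).
#' @export
screenDataset <- function(x, metrics = BEV_METRICS,
                          nPermutations = 2000L,
                          transform = "required", seed = NULL,
                          alpha = 0.05) {
  metrics <- match.arg(metrics, BEV_METRICS, several.ok = TRUE)
  labs <- batchLabels(x)
  results <- stats::setNames(vector("list", length(metrics)), metrics)
  rows <- list()
  for (i in seq_along(metrics)) {
    res <- tryCatch({
      d <- featureDist(x, metrics[i], transform = transform)
      permanovaTest(d, labs, nPermutations = nPermutations,
        seed = if (is.null(seed)) NULL else iterationSeed(seed, i))
    }, error = function(e) e)
    if (methods::is(res, "PermanovaResult")) {
      results[[i]] <- res
      rows[[i]] <- data.frame(metric = metrics[i], pseudoF = res@pseudoF,
        pValue = res@pValue, reject = res@pValue < alpha, status = "ok")
    } else {
      rows[[i]] <- data.frame(metric = metrics[i], pseudoF = NA_real_,
        pValue = NA_real_, reject = NA,
        status = paste0("failed: ", conditionMessage(res)))
    }
  }
  tab <- do.call(rbind, rows)
  if (all(tab$status != "ok"))
    bevalStop("every distance metric failed; first error: ",
      tab$status[1L], class = "batcheval_error")
  list(table = tab, results = results)
}

#' Quantify per-feature batch effect sizes
#'
#' Computes the per-feature robust effect size table plus the summaries a
#' screening workflow reports: the mean absolute effect size, per-batch-
#' level mean signed effect (the grouping used to compare batches against
#' the reference), and the features ranked by absolute effect.
#'
#' @param x a [BatchExperiment-class].
#' @param nBoot bootstrap replicates per feature (default 500).
#' @param seed optional seed.
#' @param level confidence level.
#' @return A list with `table` (from [resiTable()]) and `summary` (list:
#'   `meanAbsResi`, `perLevelMean`, `ranking`).
#' @export
quantifyDataset <- function(x, nBoot = 500L, seed = NULL, level = 0.95) {
  tab <- resiTable(x, nBoot = nBoot, seed = seed, level = level)
  ok <- tab$status == "ok"
  perLevel <- tapply(tab$resi[ok], tab$level[ok], mean)
  byFeat <- tapply(abs(tab$resi[ok]), tab$feature[ok], max)
  ranking <- names(sort(byFeat, decreasing = TRUE))
  list(table = tab,
    summary = list(meanAbsResi = mean(abs(tab$resi[ok])),
      perLevelMean = perLevel, ranking = ranking))
}

#' Compare batch-effect evaluations before and after harmonization
#'
#' Screens and quantifies the input data, harmonizes it with
#' [combatAdjust()] (protecting any covariates in the container), and
#' repeats the evaluation on the harmonized data. The report pairs the two
#' arms: per-feature effect-size change, Anderson-Darling rejection
#' fractions, and PERMANOVA p-values per metric.
#'
#' @param x a [BatchExperiment-class].
#' @param covariates covariate columns to protect (default: all present).
#' @param metrics,nPermutations,transform passed to [screenDataset()].
#' @param nBoot passed to [quantifyDataset()].
#' @param alpha significance level.
#' @param seed optional seed (substreams derived per stage).
#' @return A list with elements `pre` and `post` (each holding `screen`
#'   and `quantify` results), `deltaResi` (per-feature change in absolute
#'   effect size), `adRejection` (pre/post rejection fractions), and
#'   `permanovaP` (per-metric p-values pre/post).
#' @export
compareHarmonization <- function(x, covariates = NULL,
                                 metrics = BEV_METRICS,
                                 nPermutations = 2000L, nBoot = 500L,
                                 transform = "required", alpha = 0.05,
                                 seed = NULL) {
  sub <- function(k) if (is.null(seed)) NULL else iterationSeed(seed, k)
  evalArm <- function(be, off) {
    list(screen = screenDataset(be, metrics = metrics,
        nPermutations = nPermutations, transform = transform,
        seed = sub(off + 1L), alpha = alpha),
      quantify = quantifyDataset(be, nBoot = nBoot, seed = sub(off + 2L)),
      ad = featureTestSuite(be, tests = "ad", alpha = alpha))
  }
  pre <- evalArm(x, 0L)
  harmonized <- combatAdjust(x, covariates = covariates)
  post <- evalArm(harmonized, 10L)
  preAbs <- tapply(abs(pre$quantify$table$resi), pre$quantify$table$feature,
    mean)
  postAbs <- tapply(abs(post$quantify$table$resi),
    post$quantify$table$feature, mean)
  stopifnot(identical(names(preAbs), names(postAbs)))
  list(pre = pre, post = post,
    deltaResi = data.frame(feature = names(preAbs),
      pre = as.vector(preAbs), post = as.vector(postAbs),
      delta = as.vector(postAbs - preAbs), row.names = NULL),
    adRejection = c(pre = mean(pre$ad$reject, na.rm = TRUE),
      post = mean(post$ad$reject, na.rm = TRUE)),
    permanovaP = data.frame(metric = pre$screen$table$metric,
      pre = pre$screen$table$pValue, post = post$screen$table$pValue,
      row.names = NULL))
}
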