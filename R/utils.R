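#' @keywords internal
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats rnorm runif
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. A NULL seed evaluates expr in the ambient stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible per-iteration RNG seed
#'
#' Maps a (base seed, iteration index) pair to a seed in `[1, 2^31 - 1]` by an
#' affine congruential hash, so that iteration `k` of a study is reproducible
#' from `(baseSeed, k)` alone and independent of execution order or
#' parallelism. Chaining calls (feeding the output back in as `baseSeed`)
#' derives nested substreams for arms, metrics, or bootstrap stages.
#'
#' @param baseSeed integer scalar, the study-level seed.
#' @param k non-negative integer, the iteration (or substream) index.
#' @return An integer seed suitable for [set.seed()].
#' @examples
#' iterationSeed(1, 1:3)
#' @export
iterationSeed <- function(baseSeed, k) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime; products stay exact in doubles
  s <- ((as.numeric(baseSeed) %% m) * 48271 + as.numeric(k) * 9973 + 12345) %% m
  as.integer(s %% (m - 1)) + 1L
}

## Stop with a consistent condition class so callers can distinguish
## validation failures from computation errors.
bevalStop <- function(..., class = "batcheval_error") {
  stop(errorCondition(paste0(...), class = c(class, "batcheval_error")))
}
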