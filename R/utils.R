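#' @useDynLib pepClassify, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

# Deterministic substream seeds: one study seed spawns per-patient /
# per-replicate streams so any single unit is reproducible in isolation.
# Lehmer-style mixing, kept strictly below 2^31 - 1.
childSeed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer(((s * 48271) %% 2147483647 + as.double(index) * 2654435) %% 2147483647)
}

# Evaluate expr under a local RNG state without disturbing the caller's.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Nearest-neighbour matching of query centroids (Da) onto reference centroids
# within a tolerance; returns reference indices or NA. Greedy, distance-sorted,
# each reference used once.
matchPeaks <- function(query, ref, tol) {
  out <- rep(NA_integer_, length(query))
  if (length(ref) == 0L || length(query) == 0L) return(out)
  d <- abs(outer(query, ref, "-"))
  tolm <- if (length(tol) == 1L) matrix(tol, length(query), length(ref)) else
    matrix(tol, length(query), length(ref))
  cand <- which(d <= tolm, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(out)
  cand <- cand[order(d[cand]), , drop = FALSE]
  usedQ <- logical(length(query)); usedR <- logical(length(ref))
  for (i in seq_len(nrow(cand))) {
    qi <- cand[i, 1L]; ri <- cand[i, 2L]
    if (!usedQ[qi] && !usedR[ri]) {
      out[qi] <- ri; usedQ[qi] <- TRUE; usedR[ri] <- TRUE
    }
  }
  out
}

# mass-dependent matching tolerance: max(0.3% of m/z, one grid step)
massTol <- function(mz, gridStep) pmax(0.003 * mz, gridStep)

`%||%` <- function(a, b) if (is.null(a)) b else a
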