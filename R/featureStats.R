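#' Per-peak class-comparison statistics
#'
#' For every consensus peak, computes the class-conditional mean and SD of
#' the peak area, Welch's two-sample t-test (primary, used for ranking), the
#' Wilcoxon rank-sum test, and Benjamini-Hochberg adjusted values (reported
#' for reuse; the significance call uses the raw Welch p, mirroring the
#' original raw p < 0.05 selection). Invalid samples are excluded listwise.
#'
#' @param fm a [PeakFeatureMatrix-class], or a samples-in-columns numeric
#'   matrix of areas.
#' @param labels class labels per sample, two levels ("mutant"/"wild").
#' @param alpha raw significance threshold for the `significant` column.
#' @return data.frame sorted by ascending Welch p: centroid, meanWild,
#'   sdWild, meanMutant, sdMutant, pWelch, pRankSum, pWelchBH, pRankSumBH,
#'   direction (up_in_mutant/down_in_mutant), significant.
#' @export
differentialPeaks <- function(fm, labels, alpha = 0.05) {
  if (is(fm, "PeakFeatureMatrix")) {
    keep <- qcFlags(fm) == "ok"
    x <- peakAreas(fm)[, keep, drop = FALSE]
    labels <- labels[keep]
    centroids <- peakDefinitions(fm)$centroid
  } else {
    x <- as.matrix(fm)
    centroids <- as.numeric(sub("^mz_", "", rownames(x) %||%
                                  as.character(seq_len(nrow(x)))))
  }
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("exactly two classes are required")
  g1 <- labels == "mutant"; g2 <- labels == "wild"
  if (!any(g1) || !any(g2)) { g1 <- labels == cls[1]; g2 <- labels == cls[2] }
  if (sum(g1) < 3L || sum(g2) < 3L)
    stop("each class needs at least 3 non-invalid samples")
  rows <- lapply(seq_len(nrow(x)), function(p) {
    a <- x[p, g1]; b <- x[p, g2]
    pw <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else stats::t.test(a, b)$p.value
    pr <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
    if (is.nan(pr)) pr <- 1
    data.frame(centroid = centroids[p],
               meanWild = mean(b), sdWild = stats::sd(b),
               meanMutant = mean(a), sdMutant = stats::sd(a),
               pWelch = pw, pRankSum = pr,
               direction = if (mean(a) >= mean(b)) "up_in_mutant" else "down_in_mutant",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pWelchBH <- stats::p.adjust(out$pWelch, "BH")
  out$pRankSumBH <- stats::p.adjust(out$pRankSum, "BH")
  out$significant <- out$pWelch < alpha
  out <- out[order(out$pWelch), , drop = FALSE]
  rownames(out) <- NULL
  out
}
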