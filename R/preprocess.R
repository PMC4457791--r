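#' Restrict a spectrum to the analyzed mass range
#'
#' @param spectrum a [MassSpectrum-class].
#' @param mzRange numeric length-2 interval in Da.
#' @return the trimmed spectrum.
#' @export
trimSpectrum <- function(spectrum, mzRange) {
  keep <- spectrum@mz >= mzRange[1] & spectrum@mz <= mzRange[2]
  if (sum(keep) < 2L) stop("trim range leaves fewer than 2 points")
  MassSpectrum(spectrum@sampleId, spectrum@mz[keep], spectrum@intensity[keep],
               spectrum@metadata)
}

#' Normalize a spectrum to its total ion current
#'
#' Scales intensities so the trapezoidal integral of the spectrum equals
#' `targetTic`. Shape is preserved up to one scalar; the operation is
#' idempotent.
#'
#' @param spectrum a [MassSpectrum-class].
#' @param targetTic target integral (area units), default 1.
#' @return the normalized spectrum; TIC recorded in metadata as `rawTic`.
#' @export
normalizeTIC <- function(spectrum, targetTic = 1.0) {
  tic <- pracma::trapz(spectrum@mz, spectrum@intensity)
  if (!is.finite(tic) || tic <= 0)
    stop("degenerate input: total ion current is not positive")
  md <- spectrum@metadata
  md$rawTic <- md$rawTic %||% tic
  MassSpectrum(spectrum@sampleId, spectrum@mz,
               spectrum@intensity * (targetTic / tic), md)
}

# Quadratic (3-point) apex interpolation around index i.
.parabolicApex <- function(mz, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(mz[i])
  d2 <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (d2 >= 0) return(mz[i])
  mz[i] + 0.5 * (mz[2] - mz[1]) * (y[i - 1] - y[i + 1]) / d2
}

# Prominent per-spectrum apexes for recalibration: the signal is lightly
# pre-smoothed and freed of its slowly varying baseline (rolling median), then
# local maxima with SNR >= snr are taken, top `maxPeaks` by height, apex
# positions refined by parabolic interpolation.
.prominentPeaks <- function(spectrum, snr = 5, maxPeaks = 60L) {
  y <- spectrum@intensity; mz <- spectrum@mz; n <- length(y)
  if (n >= 7L) y <- signal::sgolayfilt(y, p = 2, n = 7L)
  step <- mz[2] - mz[1]
  kw <- min(max(3L, round(30 / step)), n - 1L)
  if (kw %% 2L == 0L) kw <- kw + 1L
  if (n > kw) y <- y - stats::runmed(y, kw, endrule = "median")
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (noise == 0) noise <- .Machine$double.eps
  i <- 2:(n - 1)
  apex <- i[y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] / noise >= snr]
  if (!length(apex)) return(numeric(0))
  apex <- apex[order(y[apex], decreasing = TRUE)]
  apex <- sort(utils::head(apex, maxPeaks))
  vapply(apex, function(j) .parabolicApex(mz, y, j), numeric(1))
}

#' Recalibrate a collection of spectra on prominent common peaks
#'
#' Prominent peaks are detected per spectrum, pooled and clustered within a
#' mass-dependent tolerance; clusters present in at least `minPresence` of
#' spectra define the calibration points. Each spectrum's m/z axis is warped
#' by the least-squares affine map of its matched apex positions onto the
#' calibration targets (the cluster consensus positions, or `reference`
#' positions when known calibrant masses are supplied), then resampled onto
#' its original grid. Spectra with fewer than 2 matches, or collections with
#' fewer than 2 common clusters, are passed through unwarped and flagged.
#'
#' @param spectra list of [MassSpectrum-class] on a common grid.
#' @param minPresence minimum fraction of spectra a cluster must appear in.
#' @param matchTol matching tolerance in Da; default `max(0.3% m/z, grid step)`.
#' @param reference optional known true positions of calibration peaks (Da).
#' @param snr,maxPeaks prominence criteria for per-spectrum apex detection.
#' @return list with `spectra` (warped) and `warps` (data.frame: sample_id,
#'   scale, offset, nMatched, failed).
#' @export
recalibrateSpectra <- function(spectra, minPresence = 0.8, matchTol = NULL,
                               reference = NULL, snr = 5, maxPeaks = 60L) {
  stopifnot(length(spectra) >= 1L)
  nS <- length(spectra)
  step <- spectra[[1]]@mz[2] - spectra[[1]]@mz[1]
  apexes <- lapply(spectra, .prominentPeaks, snr = snr, maxPeaks = maxPeaks)
  pool <- data.frame(mz = unlist(apexes),
                     spec = rep(seq_len(nS), lengths(apexes)))
  identityWarps <- data.frame(sample_id = vapply(spectra, sampleId, character(1)),
                              scale = 1, offset = 0, nMatched = 0L, failed = TRUE)
  fail <- function(msg) {
    warning("recalibration error: ", msg, "; spectra passed through unwarped")
    list(spectra = spectra, warps = identityWarps)
  }
  if (nrow(pool) < 2L) return(fail("fewer than 2 prominent peaks found"))
  pool <- pool[order(pool$mz), , drop = FALSE]
  tol <- if (is.null(matchTol)) massTol(pool$mz, step) else rep(matchTol, nrow(pool))
  newCluster <- c(TRUE, diff(pool$mz) > tol[-nrow(pool)])
  pool$cluster <- cumsum(newCluster)
  presence <- tapply(pool$spec, pool$cluster, function(s) length(unique(s))) / nS
  keep <- as.integer(names(presence)[presence >= minPresence])
  if (length(keep) < 2L) return(fail("fewer than 2 matchable common peaks"))
  consensus <- vapply(keep, function(cl) stats::median(pool$mz[pool$cluster == cl]),
                      numeric(1))
  target <- consensus
  if (!is.null(reference)) {
    m <- matchPeaks(consensus, reference, tol = massTol(consensus, step) * 2)
    if (sum(!is.na(m)) < 2L) return(fail("consensus peaks do not match the reference"))
    target[!is.na(m)] <- reference[m[!is.na(m)]]
    consensus <- consensus[!is.na(m)]; target <- target[!is.na(m)]
  }
  warps <- identityWarps
  out <- spectra
  for (s in seq_len(nS)) {
    mIdx <- matchPeaks(consensus, apexes[[s]], tol = massTol(consensus, step))
    ok <- !is.na(mIdx)
    if (sum(ok) < 2L) next
    obs <- apexes[[s]][mIdx[ok]]; tgt <- target[ok]
    # affine fit with one outlier-trimming pass (a mismatched calibration
    # point otherwise tilts the whole axis)
    fit <- stats::lm.fit(cbind(1, obs), tgt)
    res <- abs(fit$residuals)
    cut <- max(3 * stats::mad(fit$residuals), 0.5)
    if (any(res > cut) && sum(res <= cut) >= 2L) {
      keepPt <- res <= cut
      fit <- stats::lm.fit(cbind(1, obs[keepPt]), tgt[keepPt])
    }
    a <- fit$coefficients[2]; b <- fit$coefficients[1]
    if (!is.finite(a) || a <= 0) next
    sp <- spectra[[s]]
    warped <- stats::approx(a * sp@mz + b, sp@intensity, xout = sp@mz,
                            rule = 2)$y
    out[[s]] <- MassSpectrum(sp@sampleId, sp@mz, warped,
                             c(sp@metadata, list(recalScale = unname(a),
                                                 recalOffset = unname(b))))
    warps$scale[s] <- a; warps$offset[s] <- b
    warps$nMatched[s] <- length(fit$residuals); warps$failed[s] <- FALSE
  }
  list(spectra = out, warps = warps)
}

#' Savitzky-Golay smoothing
#'
#' Polynomial filter smoothing; constant signals are fixed points and peak
#' areas are preserved for peaks wider than the window. `order = 0` is a
#' moving average.
#'
#' @param spectrum a [MassSpectrum-class].
#' @param window filter window in Da (converted to an odd number of grid
#'   points; must span at least 3 points).
#' @param order polynomial order.
#' @return the smoothed spectrum.
#' @export
smoothSpectrum <- function(spectrum, window = 2, order = 3) {
  step <- spectrum@mz[2] - spectrum@mz[1]
  w <- round(window / step)
  if (w %% 2 == 0) w <- w + 1L
  if (w < 3L) stop("smoothing window must span at least 3 grid points")
  if (w > length(spectrum@mz)) stop("smoothing window wider than the spectrum")
  if (order >= w) w <- order + 1L + (order %% 2L)  # keep p < n
  y <- signal::sgolayfilt(spectrum@intensity, p = order, n = w)
  MassSpectrum(spectrum@sampleId, spectrum@mz, y, spectrum@metadata)
}

#' Morphological opening with a flat structuring element
#'
#' Erosion (rolling minimum) followed by dilation (rolling maximum) with the
#' same centered flat element; windows shrink at the signal boundaries. The
#' operation is idempotent and never exceeds the input.
#'
#' @param x numeric signal.
#' @param width element length in points (made odd).
#' @return the opened signal.
#' @export
morphologicalOpening <- function(x, width) {
  k <- as.integer(width)
  if (k %% 2L == 0L) k <- k + 1L
  if (k < 1L) stop("element width must be >= 1")
  .rollMax(.rollMin(as.numeric(x), k), k)
}

#' Top-hat baseline subtraction
#'
#' Subtracts the morphological opening of the signal computed with a flat
#' structuring element spanning `minWidthFrac` of the analyzed mass range
#' (minimum baseline width). On a noisy signal the opening tracks the lower
#' noise envelope, which leaves a small positive stochastic offset between
#' peaks; when `zeroLevelWindow` is non-NULL this residual floor is removed
#' by subtracting a rolling median (computed over windows wide enough to be
#' unaffected by the peaks themselves). The pure opening subtraction is
#' nonnegative everywhere; the refined signal fluctuates symmetrically around
#' zero between peaks (area integration later clips at the zero level).
#' Features narrower than the element are preserved.
#'
#' @param spectrum a (smoothed) [MassSpectrum-class].
#' @param minWidthFrac element length as a fraction of the mass range, in (0, 1].
#' @param zeroLevelWindow width (Da) of the rolling-median zero-level
#'   refinement; `NULL` for the pure opening subtraction.
#' @return the baseline-subtracted spectrum.
#' @export
subtractBaselineTophat <- function(spectrum, minWidthFrac = 0.10,
                                   zeroLevelWindow = 30) {
  if (minWidthFrac <= 0 || minWidthFrac > 1)
    stop("minWidthFrac must be in (0, 1]")
  mz <- spectrum@mz
  step <- mz[2] - mz[1]
  k <- max(3L, round(minWidthFrac * (mz[length(mz)] - mz[1]) / step))
  y <- spectrum@intensity - morphologicalOpening(spectrum@intensity, k)
  if (!is.null(zeroLevelWindow)) {
    kw <- min(round(zeroLevelWindow / step), length(y) - 1L)
    if (kw %% 2L == 0L) kw <- kw + 1L
    if (kw >= 3L)
      y <- y - stats::runmed(y, kw, endrule = "median")
  }
  MassSpectrum(spectrum@sampleId, mz, y, spectrum@metadata)
}

#' Robust local noise estimate
#'
#' Median-absolute-deviation estimate (scaled to the Gaussian sigma) computed
#' in consecutive windows and linearly interpolated to every grid point.
#' Robust against sparse tall peaks.
#'
#' @param spectrum a baseline-subtracted [MassSpectrum-class].
#' @param window window width in Da.
#' @return numeric vector, one noise sigma per grid point.
#' @export
estimateNoise <- function(spectrum, window = 300) {
  y <- spectrum@intensity; mz <- spectrum@mz
  step <- mz[2] - mz[1]
  w <- max(5L, round(window / step))
  n <- length(y)
  starts <- seq(1L, n, by = w)
  centers <- pmin(starts + (w - 1) / 2, n)
  est <- vapply(starts, function(s) {
    stats::mad(y[s:min(s + w - 1L, n)])
  }, numeric(1))
  if (length(est) == 1L) return(rep(est, n))
  stats::approx(mz[round(centers)], est, xout = mz, rule = 2)$y
}

#' Detect peaks on a cohort mean spectrum
#'
#' Segments the spectrum at its local minima; a segment becomes a peak when
#' its apex signal-to-noise ratio reaches `snrThreshold`. Adjacent peaks
#' whose shared valley exceeds 75% of the lower apex are merged (one split
#' maximum). Bounds are the flanking minima, tightened to zero-crossings;
#' centroids are intensity-weighted means within the bounds. Bounds are
#' pairwise non-overlapping.
#'
#' @param meanSpectrum the average [MassSpectrum-class] of the preprocessed
#'   cohort.
#' @param noise per-point noise vector (see [estimateNoise()]) or a scalar.
#' @param snrThreshold minimum apex SNR, default 5.
#' @return data.frame of peak definitions: index, centroid, leftBound,
#'   rightBound, apex, snr. Zero rows when nothing reaches the threshold.
#' @export
detectPeaks <- function(meanSpectrum, noise = estimateNoise(meanSpectrum),
                        snrThreshold = 5) {
  y <- meanSpectrum@intensity; mz <- meanSpectrum@mz; n <- length(y)
  if (length(noise) == 1L) noise <- rep(noise, n)
  empty <- data.frame(index = integer(0), centroid = numeric(0),
                      leftBound = numeric(0), rightBound = numeric(0),
                      apex = numeric(0), snr = numeric(0))
  i <- 2:(n - 1)
  minima <- i[y[i] <= y[i - 1] & y[i] < y[i + 1]]
  bnd <- unique(c(1L, minima, n))
  segs <- data.frame(from = bnd[-length(bnd)], to = bnd[-1])
  segs$apexIdx <- vapply(seq_len(nrow(segs)), function(s) {
    idx <- segs$from[s]:segs$to[s]
    idx[which.max(y[idx])]
  }, integer(1))
  segs$apex <- y[segs$apexIdx]
  segs$snr <- segs$apex / pmax(noise[segs$apexIdx], .Machine$double.eps)
  segs <- segs[segs$snr >= snrThreshold & segs$apex > 0, , drop = FALSE]
  if (!nrow(segs)) return(empty)
  # merge a maximum split by a shallow valley (valley > 75% of lower apex)
  repeat {
    if (nrow(segs) < 2L) break
    adj <- which(segs$to[-nrow(segs)] == segs$from[-1])
    merged <- FALSE
    for (a in adj) {
      valley <- y[segs$to[a]]
      if (valley > 0.75 * min(segs$apex[a], segs$apex[a + 1])) {
        segs$to[a] <- segs$to[a + 1]
        if (segs$apex[a + 1] > segs$apex[a]) {
          segs$apex[a] <- segs$apex[a + 1]; segs$apexIdx[a] <- segs$apexIdx[a + 1]
          segs$snr[a] <- segs$snr[a + 1]
        }
        segs <- segs[-(a + 1), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # tighten bounds to zero-crossings inside the segment
  for (s in seq_len(nrow(segs))) {
    idx <- segs$from[s]:segs$apexIdx[s]
    z <- idx[y[idx] <= 0]
    if (length(z)) segs$from[s] <- max(z)
    idx <- segs$apexIdx[s]:segs$to[s]
    z <- idx[y[idx] <= 0]
    if (length(z)) segs$to[s] <- min(z)
  }
  centroid <- vapply(seq_len(nrow(segs)), function(s) {
    idx <- segs$from[s]:segs$to[s]
    w <- pmax(y[idx], 0)
    if (sum(w) == 0) return(mz[segs$apexIdx[s]])
    sum(mz[idx] * w) / sum(w)
  }, numeric(1))
  out <- data.frame(index = seq_len(nrow(segs)), centroid = centroid,
                    leftBound = mz[segs$from], rightBound = mz[segs$to],
                    apex = segs$apex, snr = segs$snr)
  out[out$leftBound < out$centroid & out$centroid < out$rightBound, ,
      drop = FALSE]
}

#' Zero-level peak-area integration
#'
#' Trapezoidal integral of the (nonnegative part of the) intensity between
#' each peak's bounds, down to the zero level. With `recentroid = TRUE` the
#' integration window is shifted to the local apex of this spectrum within a
#' relative tolerance of the consensus centroid, compensating residual
#' calibration error.
#'
#' @param spectrum a baseline-subtracted, normalized [MassSpectrum-class].
#' @param peaks peak-definition data.frame from [detectPeaks()].
#' @param recentroid logical.
#' @param recentroidTol maximum relative m/z shift (default 0.3%).
#' @return numeric vector of nonnegative areas, one per peak.
#' @export
integrateAreas <- function(spectrum, peaks, recentroid = TRUE,
                           recentroidTol = 0.003) {
  mz <- spectrum@mz; y <- spectrum@intensity
  n <- length(mz)
  lo <- mz[1]; hi <- mz[n]
  span <- function(a, b) {  # grid indices with a <= mz <= b
    i1 <- findInterval(a - 1e-9, mz) + 1L
    i2 <- findInterval(b + 1e-9, mz)
    if (i1 > i2) integer(0) else i1:i2
  }
  vapply(seq_len(nrow(peaks)), function(p) {
    l <- peaks$leftBound[p]; r <- peaks$rightBound[p]; cen <- peaks$centroid[p]
    if (l < lo - 1e-9 || r > hi + 1e-9)
      stop(sprintf("peak at m/z %.2f lies outside the spectrum range", cen))
    shift <- 0
    if (recentroid) {
      tol <- recentroidTol * cen
      win <- span(max(lo, cen - tol), min(hi, cen + tol))
      if (length(win) >= 3L) {
        apex <- win[which.max(y[win])]
        shift <- max(-tol, min(tol, mz[apex] - cen))
      }
    }
    idx <- span(max(lo, l + shift), min(hi, r + shift))
    if (length(idx) < 2L) return(0)
    max(0, pracma::trapz(mz[idx], pmax(y[idx], 0)))
  }, numeric(1))
}

#' Average a collection of spectra on a common grid
#'
#' @param spectra list of [MassSpectrum-class] sharing one m/z grid.
#' @return the point-wise mean [MassSpectrum-class].
#' @export
averageSpectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  mz <- spectra[[1]]@mz
  for (sp in spectra)
    if (length(sp@mz) != length(mz) || any(abs(sp@mz - mz) > 1e-9))
      stop("spectra must share a common m/z grid")
  y <- Reduce(`+`, lapply(spectra, intensityValues)) / length(spectra)
  MassSpectrum("mean", mz, y)
}

#' Run the full preprocessing workflow and build the feature matrix
#'
#' Trims each spectrum to the analyzed range, normalizes to total ion
#' current, recalibrates the collection on prominent common peaks, smooths
#' (Savitzky-Golay), subtracts the top-hat baseline, estimates per-spectrum
#' noise, detects consensus peaks on the cohort mean spectrum at the SNR
#' threshold, and integrates per-spectrum areas at the consensus bounds.
#' A spectrum is flagged invalid when fewer than `qcMinFraction` of the
#' consensus peaks reach a local SNR of `qcMinSnr` in that spectrum; invalid
#' samples carry all-missing areas.
#'
#' @param spectra list of [MassSpectrum-class] on a common grid (>= 2).
#' @param mzRange analyzed range in Da, or NULL to keep the native range.
#' @param targetTic normalization target.
#' @param recalibrate logical; skip axis recalibration when FALSE.
#' @param smoothWindow,smoothOrder Savitzky-Golay settings (Da, order).
#' @param tophatFrac minimum baseline width as a fraction of the range.
#' @param noiseWindow noise-estimation window (Da).
#' @param snrThreshold peak-detection SNR threshold.
#' @param qcMinSnr,qcMinFraction per-sample spectrum quality rule.
#' @param peaks optional fixed peak definitions (e.g. the training-cohort
#'   consensus, for integrating a blinded cohort at the same bounds); when
#'   supplied, detection on the mean spectrum is skipped.
#' @return a [PeakFeatureMatrix-class]; processing parameters and
#'   recalibration warps are stored in its `metadata()`.
#' @export
buildFeatureMatrix <- function(spectra, mzRange = NULL, targetTic = 1.0,
                               recalibrate = TRUE, smoothWindow = 2,
                               smoothOrder = 3, tophatFrac = 0.10,
                               noiseWindow = 300, snrThreshold = 5,
                               qcMinSnr = 2, qcMinFraction = 0.5,
                               peaks = NULL) {
  if (length(spectra) < 2L) stop("need at least 2 spectra")
  ids <- vapply(spectra, sampleId, character(1))
  if (!is.null(mzRange)) spectra <- lapply(spectra, trimSpectrum, mzRange = mzRange)
  normOk <- rep(TRUE, length(spectra))
  spectra <- lapply(seq_along(spectra), function(i) {
    tryCatch(normalizeTIC(spectra[[i]], targetTic),
             error = function(e) { normOk[i] <<- FALSE; spectra[[i]] })
  })
  if (!any(normOk)) stop("cohort error: all spectra degenerate")
  warps <- NULL
  if (recalibrate) {
    rec <- suppressWarnings(recalibrateSpectra(spectra))
    spectra <- rec$spectra; warps <- rec$warps
  }
  spectra <- lapply(spectra, smoothSpectrum, window = smoothWindow,
                    order = smoothOrder)
  spectra <- lapply(spectra, subtractBaselineTophat, minWidthFrac = tophatFrac)
  noise <- lapply(spectra, estimateNoise, window = noiseWindow)
  meanSpec <- averageSpectra(spectra)
  if (is.null(peaks))
    peaks <- detectPeaks(meanSpec, estimateNoise(meanSpec, window = noiseWindow),
                         snrThreshold = snrThreshold)
  if (!nrow(peaks)) stop("cohort error: no peaks detected on the mean spectrum")
  mz <- meanSpec@mz
  nPk <- nrow(peaks)
  areas <- matrix(NA_real_, nrow = nPk, ncol = length(spectra))
  qc <- rep("invalid", length(spectra))
  cenIdx <- pmin(pmax(findInterval(peaks$centroid, mz), 1L), length(mz))
  pkWin <- lapply(seq_len(nPk), function(p) {
    i1 <- findInterval(peaks$leftBound[p] - 1e-9, mz) + 1L
    i2 <- findInterval(peaks$rightBound[p] + 1e-9, mz)
    if (i1 > i2) integer(0) else i1:i2
  })
  for (i in seq_along(spectra)) {
    if (!normOk[i]) next
    yi <- spectra[[i]]@intensity
    localSnr <- vapply(seq_len(nPk), function(p) {
      if (!length(pkWin[[p]])) return(0)
      max(yi[pkWin[[p]]]) / max(noise[[i]][cenIdx[p]], .Machine$double.eps)
    }, numeric(1))
    if (mean(localSnr >= qcMinSnr) >= qcMinFraction) {
      qc[i] <- "ok"
      areas[, i] <- integrateAreas(spectra[[i]], peaks)
    }
  }
  if (!any(qc == "ok")) stop("cohort error: all spectra invalid")
  colnames(areas) <- ids
  rownames(areas) <- sprintf("mz_%.2f", peaks$centroid)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(area = areas),
    rowData = S4Vectors::DataFrame(peaks),
    colData = S4Vectors::DataFrame(sample_id = ids, qc_flag = qc,
                                   row.names = ids))
  S4Vectors::metadata(se) <- list(
    params = list(targetTic = targetTic, smoothWindow = smoothWindow,
                  smoothOrder = smoothOrder, tophatFrac = tophatFrac,
                  noiseWindow = noiseWindow, snrThreshold = snrThreshold,
                  qcMinSnr = qcMinSnr, qcMinFraction = qcMinFraction),
    warps = warps)
  new("PeakFeatureMatrix", se)
}
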