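#' MassSpectrum: a single profile mass spectrum
#'
#' A raw or processed MALDI-TOF profile spectrum: a strictly increasing m/z
#' grid (Da) with matching intensities (arbitrary units) and free-form
#' metadata (seed, injected calibration distortion, QC flags, ...).
#'
#' Raw spectra as produced by [simulateSpectrum()] or [readSpectrum()] have
#' nonnegative intensities; intermediate processed spectra (e.g. after
#' smoothing) may dip below zero, so the class itself only requires finite
#' values.
#'
#' @slot sampleId single sample identifier.
#' @slot mz numeric, strictly increasing m/z grid in Da.
#' @slot intensity numeric, same length as `mz`, finite.
#' @slot metadata named list of free-form annotations.
#' @export
setClass("MassSpectrum",
  slots = c(sampleId = "character", mz = "numeric", intensity = "numeric",
            metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
    if (length(object@mz) != length(object@intensity))
      msg <- c(msg, "mz and intensity lengths differ")
    if (length(object@mz) < 2L) msg <- c(msg, "a spectrum needs at least 2 points")
    if (length(object@mz) >= 2L && any(diff(object@mz) <= 0))
      msg <- c(msg, "mz must be strictly increasing")
    if (anyNA(object@intensity) || any(!is.finite(object@intensity)))
      msg <- c(msg, "intensities must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a MassSpectrum
#'
#' @param sampleId sample identifier.
#' @param mz strictly increasing m/z values (Da). Unsorted input is sorted
#'   with a warning; duplicated m/z values are an error.
#' @param intensity intensities, same length as `mz`.
#' @param metadata named list.
#' @return a [MassSpectrum-class] object.
#' @export
MassSpectrum <- function(sampleId, mz, intensity, metadata = list()) {
  if (is.unsorted(mz, strictly = FALSE)) {
    warning("m/z values not sorted; sorting ascending")
    o <- order(mz); mz <- mz[o]; intensity <- intensity[o]
  }
  new("MassSpectrum", sampleId = as.character(sampleId), mz = as.numeric(mz),
      intensity = as.numeric(intensity), metadata = metadata)
}

setMethod("show", "MassSpectrum", function(object) {
  cat(sprintf("MassSpectrum '%s': %d points, m/z %.2f-%.2f Da\n",
              object@sampleId, length(object@mz), min(object@mz), max(object@mz)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' SimulationConfig: parameters of the synthetic spectrum generator
#'
#' Defines the study conditions a simulated cohort is drawn under: cohort
#' sizes, the acquisition grid, the catalogue of class-discriminating and
#' background peaks, the peak-width (resolution) model, baseline, noise,
#' per-spectrum total-ion-current spread, calibration error and the rate of
#' low-quality (unclassifiable) spectra.
#'
#' @slot nMutant,nWild cohort sizes per true class.
#' @slot mzRange recorded mass range in Da.
#' @slot gridStep acquisition grid step in Da.
#' @slot discriminatingPeaks data.frame: centroid, meanWild, sdWild,
#'   meanMutant, sdMutant (peak areas, arbitrary units).
#' @slot backgroundPeaks data.frame: centroid, mean, sd (class-independent).
#' @slot resolution relative peak width: Gaussian sigma = centroid * resolution.
#' @slot baselineAmplitude,baselineDecay,baselineConstant smooth baseline
#'   b(m) = amplitude * exp(-(m - min)/decay) + constant.
#' @slot noiseSigma iid Gaussian intensity noise, raw units.
#' @slot ticVariation sdlog of the per-spectrum multiplicative intensity factor.
#' @slot calibrationScaleMax,calibrationOffsetMax bounds of the per-spectrum
#'   affine m/z distortion (scale is 1 +/- scaleMax, offset in Da).
#' @slot invalidRate probability a spectrum is rendered low-quality.
#' @slot seed integer study seed; spawns per-patient substreams.
#' @export
setClass("SimulationConfig",
  slots = c(nMutant = "integer", nWild = "integer", mzRange = "numeric",
            gridStep = "numeric", discriminatingPeaks = "data.frame",
            backgroundPeaks = "data.frame", resolution = "numeric",
            baselineAmplitude = "numeric", baselineDecay = "numeric",
            baselineConstant = "numeric", noiseSigma = "numeric",
            ticVariation = "numeric", calibrationScaleMax = "numeric",
            calibrationOffsetMax = "numeric", invalidRate = "numeric",
            seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nMutant < 0L || object@nWild < 0L) msg <- c(msg, "cohort sizes must be >= 0")
    if (object@nMutant + object@nWild < 1L) msg <- c(msg, "empty cohort")
    if (length(object@mzRange) != 2L || diff(object@mzRange) <= 0)
      msg <- c(msg, "mzRange must be an increasing interval")
    if (object@gridStep <= 0) msg <- c(msg, "gridStep must be > 0")
    dp <- object@discriminatingPeaks
    need <- c("centroid", "meanWild", "sdWild", "meanMutant", "sdMutant")
    if (!all(need %in% names(dp))) msg <- c(msg, "discriminatingPeaks missing columns")
    else if (nrow(dp) == 0L && nrow(object@backgroundPeaks) == 0L)
      msg <- c(msg, "empty peak catalogue")
    else if (nrow(dp) && any(c(dp$sdWild, dp$sdMutant) <= 0))
      msg <- c(msg, "all peak-area SDs must be > 0")
    bp <- object@backgroundPeaks
    if (nrow(bp) && any(bp$sd <= 0)) msg <- c(msg, "background SDs must be > 0")
    if (object@invalidRate < 0 || object@invalidRate > 1)
      msg <- c(msg, "invalidRate must be in [0, 1]")
    if (object@resolution <= 0) msg <- c(msg, "resolution must be > 0")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' OutcomeParams: parameters of the clinical-outcome generator
#'
#' Class-conditional probabilities of objective response (CR+PR) and disease
#' control (CR+PR+SD) under RECIST, exponential PFS/OS medians (months), and
#' an administrative right-censoring horizon.
#'
#' @slot pObjectiveResponse,pDiseaseControl named numeric (mutant, wild).
#' @slot pfsMedian,osMedian named numeric medians in months.
#' @slot censorHorizon months of follow-up; later times are censored.
#' @slot seed integer.
#' @export
setClass("OutcomeParams",
  slots = c(pObjectiveResponse = "numeric", pDiseaseControl = "numeric",
            pfsMedian = "numeric", osMedian = "numeric",
            censorHorizon = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    cls <- c("mutant", "wild")
    for (nm in c("pObjectiveResponse", "pDiseaseControl", "pfsMedian", "osMedian"))
      if (!all(cls %in% names(slot(object, nm))))
        msg <- c(msg, sprintf("%s must be named for classes mutant and wild", nm))
    if (!length(msg)) {
      if (any(object@pObjectiveResponse < 0 | object@pObjectiveResponse > 1) ||
          any(object@pDiseaseControl < 0 | object@pDiseaseControl > 1))
        msg <- c(msg, "probabilities must be in [0, 1]")
      if (any(object@pDiseaseControl[cls] < object@pObjectiveResponse[cls]))
        msg <- c(msg, "disease-control probability must be >= objective-response probability")
      if (any(object@pfsMedian <= 0) || any(object@osMedian <= 0))
        msg <- c(msg, "survival medians must be > 0")
    }
    if (length(msg)) msg else TRUE
  }
)

#' PeakFeatureMatrix: samples x peak-areas container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `area` assay
#' (peaks in rows, samples in columns), consensus peak definitions in
#' `rowData` (centroid, leftBound, rightBound, snr) and per-sample QC flags
#' in `colData` (`qc_flag`, "ok" or "invalid"). Invalid samples carry
#' all-missing areas.
#'
#' @export
setClass("PeakFeatureMatrix", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"area" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "missing 'area' assay")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("centroid", "leftBound", "rightBound") %in% names(rd)))
      msg <- c(msg, "rowData must carry centroid, leftBound, rightBound")
    else if (nrow(rd) && (any(rd$leftBound >= rd$centroid) || any(rd$centroid >= rd$rightBound)))
      msg <- c(msg, "peak bounds must satisfy left < centroid < right")
    cd <- SummarizedExperiment::colData(object)
    if (!"qc_flag" %in% names(cd)) msg <- c(msg, "colData must carry qc_flag")
    else if (!all(cd$qc_flag %in% c("ok", "invalid")))
      msg <- c(msg, "qc_flag values must be 'ok' or 'invalid'")
    a <- SummarizedExperiment::assay(object, "area")
    if (nrow(a) && ncol(a)) {
      ok <- cd$qc_flag == "ok"
      if (any(ok) && anyNA(a[, ok, drop = FALSE]))
        msg <- c(msg, "areas of ok samples must be non-missing")
      v <- a[, ok, drop = FALSE]
      if (length(v) && (any(!is.finite(v)) || any(v < 0)))
        msg <- c(msg, "areas must be finite and >= 0")
    }
    if (length(msg)) msg else TRUE
  }
)

#' ClassifierModel: a trained mutation-status classifier
#'
#' @slot kind "GA", "SNN" or "QC".
#' @slot selectedPeaks centroids (Da) of the peaks the model uses.
#' @slot decisionData kind-specific decision data: GA carries standardized
#'   training exemplars and k; SNN carries class prototypes and widths; QC
#'   carries per-peak weights and class means.
#' @slot scaling per-peak center/scale applied at training time.
#' @slot classLabels the two class labels, c("mutant", "wild").
#' @export
setClass("ClassifierModel",
  slots = c(kind = "character", selectedPeaks = "numeric",
            decisionData = "list", scaling = "list", classLabels = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("GA", "SNN", "QC")) msg <- c(msg, "kind must be GA, SNN or QC")
    if (length(object@selectedPeaks) < 1L) msg <- c(msg, "model selects no peaks")
    if (length(object@classLabels) != 2L) msg <- c(msg, "need exactly 2 class labels")
    if (object@kind == "GA") {
      k <- object@decisionData$k
      if (is.null(k) || k %% 2L == 0L || k < 1L) msg <- c(msg, "GA-kNN needs odd k >= 1")
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel <%s>: %d peaks (m/z %s)\n", object@kind,
              length(object@selectedPeaks),
              paste(round(object@selectedPeaks, 2), collapse = ", ")))
})

#' CVResult: repeated random-split cross-validation summary
#'
#' @slot crossValidationPct mean holdout accuracy over the iterations (%).
#' @slot recognitionPct resubstitution accuracy of the final model (%).
#' @slot perIteration holdout accuracies per iteration (%).
#' @slot settings list: leaveOutPct, iterations, seed.
#' @export
setClass("CVResult",
  slots = c(crossValidationPct = "numeric", recognitionPct = "numeric",
            perIteration = "numeric", settings = "list"),
  validity = function(object) {
    ok <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 100
    msg <- character()
    if (!ok(object@crossValidationPct)) msg <- c(msg, "crossValidationPct out of [0,100]")
    if (!ok(object@recognitionPct)) msg <- c(msg, "recognitionPct out of [0,100]")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: cross-validation %.2f%%, recognition %.2f%% (%d x %d%% holdout)\n",
              object@crossValidationPct, object@recognitionPct,
              length(object@perIteration),
              object@settings$leaveOutPct %||% NA))
})
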