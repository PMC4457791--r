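#' @rdname MassSpectrum-class
#' @param object,x a package object.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname MassSpectrum-class
#' @export
setGeneric("mzValues", function(object) standardGeneric("mzValues"))

#' @rdname MassSpectrum-class
#' @export
setGeneric("intensityValues", function(object) standardGeneric("intensityValues"))

#' @rdname MassSpectrum-class
#' @export
setGeneric("spectrumMetadata", function(object) standardGeneric("spectrumMetadata"))

#' @rdname PeakFeatureMatrix-class
#' @param object a `PeakFeatureMatrix`.
#' @export
setGeneric("peakAreas", function(object) standardGeneric("peakAreas"))

#' @rdname PeakFeatureMatrix-class
#' @export
setGeneric("peakDefinitions", function(object) standardGeneric("peakDefinitions"))

#' @rdname PeakFeatureMatrix-class
#' @export
setGeneric("qcFlags", function(object) standardGeneric("qcFlags"))

#' @export
#' @rdname MassSpectrum-class
setMethod("sampleId", "MassSpectrum", function(object) object@sampleId)

#' @export
#' @rdname MassSpectrum-class
setMethod("mzValues", "MassSpectrum", function(object) object@mz)

#' @export
#' @rdname MassSpectrum-class
setMethod("intensityValues", "MassSpectrum", function(object) object@intensity)

#' @export
#' @rdname MassSpectrum-class
setMethod("spectrumMetadata", "MassSpectrum", function(object) object@metadata)

#' @export
#' @rdname PeakFeatureMatrix-class
setMethod("peakAreas", "PeakFeatureMatrix", function(object)
  SummarizedExperiment::assay(object, "area"))

#' @export
#' @rdname PeakFeatureMatrix-class
setMethod("peakDefinitions", "PeakFeatureMatrix", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)))

#' @export
#' @rdname PeakFeatureMatrix-class
setMethod("qcFlags", "PeakFeatureMatrix", function(object)
  stats::setNames(SummarizedExperiment::colData(object)$qc_flag, colnames(object)))

#' @export
#' @rdname PeakFeatureMatrix-class
setMethod("sampleId", "PeakFeatureMatrix", function(object) colnames(object))

#' Accessors for CVResult
#' @rdname CVResult-class
#' @param object a `CVResult`.
#' @export
setGeneric("crossValidationPct", function(object) standardGeneric("crossValidationPct"))

#' @rdname CVResult-class
#' @export
setGeneric("recognitionPct", function(object) standardGeneric("recognitionPct"))

#' @export
#' @rdname CVResult-class
setMethod("crossValidationPct", "CVResult", function(object) object@crossValidationPct)

#' @export
#' @rdname CVResult-class
setMethod("recognitionPct", "CVResult", function(object) object@recognitionPct)

#' @rdname ClassifierModel-class
#' @param object a `ClassifierModel`.
#' @export
setGeneric("selectedPeaks", function(object) standardGeneric("selectedPeaks"))

#' @export
#' @rdname ClassifierModel-class
setMethod("selectedPeaks", "ClassifierModel", function(object) object@selectedPeaks)
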