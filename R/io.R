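#' Read a profile spectrum from disk
#'
#' Supported dialects: `xy` (two whitespace-separated numeric columns,
#' `#`-comments and blank lines ignored), `csv` (two comma-separated columns,
#' optional header), and `mzml` (profile mzML, first spectrum, read via mzR).
#' Parse failures name the offending line. Unsorted m/z values are sorted
#' with a warning; duplicated m/z values violate the spectrum invariants and
#' are an error.
#'
#' @param path file to read.
#' @param format one of "xy", "csv", "mzml". Default guesses from the
#'   file extension.
#' @param sampleIdLabel sample identifier; defaults to the file name.
#' @return a [MassSpectrum-class].
#' @export
readSpectrum <- function(path, format = c("auto", "xy", "csv", "mzml"),
                         sampleIdLabel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), csv = "csv",
                     mzml = "mzml", "xy")
  sid <- sampleIdLabel %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("mzML support requires the mzR package")
    f <- mzR::openMSfile(path)
    on.exit(mzR::close(f))
    p <- mzR::peaks(f, 1L)
    return(.spectrumFromColumns(p[, 1], p[, 2], sid))
  }
  lines <- readLines(path)
  sep <- if (format == "csv") "," else "[[:space:]]+"
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (format == "csv" && length(keep)) {
    first <- strsplit(trimws(lines[keep[1]]), sep)[[1]]
    if (any(is.na(suppressWarnings(as.numeric(first))))) keep <- keep[-1]
  }
  mz <- numeric(length(keep)); intensity <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), sep)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != 2L)
      stop(sprintf("parse error at line %d of %s: expected 2 columns, found %d",
                   ln, basename(path), length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("parse error at line %d of %s: non-numeric entry '%s'",
                   ln, basename(path), fields[which(is.na(vals))[1]]))
    mz[i] <- vals[1]; intensity[i] <- vals[2]
  }
  .spectrumFromColumns(mz, intensity, sid, path)
}

.spectrumFromColumns <- function(mz, intensity, sid, path = "<input>") {
  if (length(mz) < 2L)
    stop(sprintf("parse error in %s: fewer than 2 data points", basename(path)))
  if (anyDuplicated(mz))
    stop(sprintf("parse error in %s: duplicated m/z value %.6g", basename(path),
                 mz[which(duplicated(mz))[1]]))
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop(sprintf("parse error in %s: intensities must be finite and >= 0",
                 basename(path)))
  MassSpectrum(sid, mz, intensity)
}

#' Write a profile spectrum to disk
#'
#' `xy` and `csv` serialize with 12 significant digits (lossless round-trips
#' at >= 1e-9 relative precision); `mzml` writes an uncompressed profile
#' mzML via mzR.
#'
#' @param spectrum a [MassSpectrum-class].
#' @param path output file.
#' @param format one of "xy", "csv", "mzml".
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path, format = c("xy", "csv", "mzml")) {
  format <- match.arg(format)
  stopifnot(is(spectrum, "MassSpectrum"))
  mz <- spectrum@mz; y <- spectrum@intensity
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("mzML support requires the mzR package")
    hdr <- data.frame(
      seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
      peaksCount = length(mz), totIonCurrent = sum(y), retentionTime = 0,
      basePeakMZ = mz[which.max(y)], basePeakIntensity = max(y),
      collisionEnergy = 0, ionisationEnergy = 0, lowMZ = min(mz), highMZ = max(mz),
      precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = NA_character_,
      spectrumId = paste0("scan=", 1L), centroided = FALSE,
      ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
      isolationWindowUpperOffset = NA_real_,
      scanWindowLowerLimit = min(mz), scanWindowUpperLimit = max(mz))
    mzR::writeMSData(list(cbind(mz, y)), file = path, header = hdr,
                     outformat = "mzml")
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else " "
  lines <- paste(sprintf("%.12g", mz), sprintf("%.12g", y), sep = sep)
  if (format == "csv") lines <- c("mz,intensity", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write tabular artifacts (cohort metadata, feature tables)
#'
#' Plain CSV with a header row; missing values serialized as empty fields.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `readTable`: a data.frame; `writeTable`: `path`, invisibly.
#' @export
writeTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Write a feature matrix and its peak definitions as CSV
#'
#' @param fm a [PeakFeatureMatrix-class].
#' @param areasPath,peaksPath output CSVs (samples x peaks table with
#'   sample_id and qc_flag columns; peak-definition table).
#' @return invisibly, the two paths.
#' @export
writeFeatureMatrix <- function(fm, areasPath, peaksPath) {
  stopifnot(is(fm, "PeakFeatureMatrix"))
  a <- t(peakAreas(fm))
  colnames(a) <- sprintf("mz_%.2f", peakDefinitions(fm)$centroid)
  tab <- data.frame(sample_id = colnames(fm), qc_flag = unname(qcFlags(fm)),
                    a, check.names = FALSE)
  writeTable(tab, areasPath)
  writeTable(peakDefinitions(fm), peaksPath)
  invisible(c(areasPath, peaksPath))
}
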