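#' Class-discriminating peak catalogue used by the default generator
#'
#' Nine serum peptide peaks whose class-conditional area means and SDs drive
#' the simulated separation between EGFR TKI-sensitive mutant and wild-type
#' cohorts, plus the weakly informative peak at m/z 4438.43 (no published
#' effect size exists for it; its class means are separated by 0.5 pooled SD).
#'
#' @return data.frame with columns centroid, meanWild, sdWild, meanMutant,
#'   sdMutant (areas in arbitrary units, centroids in Da).
#' @export
defaultDiscriminatingPeaks <- function() {
  tab <- data.frame(
    centroid   = c(1365.1, 1866.47, 3315.75, 3883.79, 3956.66,
                   4092.4, 4585.05, 4643.49, 5866.96),
    meanWild   = c(15.96, 638.6, 40.92, 7.13, 32.42, 4.57, 4.04, 30.23, 1.8),
    sdWild     = c(5.37, 548.7, 26.8, 2.97, 31.73, 1.63, 1.67, 14.08, 0.97),
    meanMutant = c(9.1, 170.42, 77.98, 12.26, 56.98, 10, 8.15, 48.54, 3.96),
    sdMutant   = c(4.01, 124.03, 59.56, 5.33, 35.78, 4.29, 3.3, 23.42, 3.18))
  # weak classifier peak: 0.5 pooled-SD class separation, higher in mutants
  weak <- data.frame(centroid = 4438.43, meanWild = 20, sdWild = 6,
                     meanMutant = 23, sdMutant = 6)
  out <- rbind(tab, weak)
  out[order(out$centroid), , drop = FALSE]
}

#' Background (non-discriminating) peak catalogue
#'
#' A fixed catalogue of class-independent peaks filling the spectrum to the
#' ~129 total peaks a serum peptidome profile typically yields. The catalogue
#' is deterministic (internally seeded) so the default configuration is a
#' constant: centroids uniform over the recorded range, kept >= 15 Da away
#' from the discriminating centroids; log-normal mean areas.
#'
#' @param n number of background peaks.
#' @param mzRange recorded range (Da).
#' @return data.frame with columns centroid, mean, sd.
#' @export
defaultBackgroundPeaks <- function(n = 120L, mzRange = c(800, 10000)) {
  keepOut <- defaultDiscriminatingPeaks()$centroid
  withSeed(73421L, {
    lo <- mzRange[1] + 50; hi <- mzRange[2] - 50
    cen <- numeric(0)
    while (length(cen) < n) {
      cand <- stats::runif(n, lo, hi)
      ok <- vapply(cand, function(m) all(abs(m - c(keepOut, cen)) > 15), logical(1))
      cen <- c(cen, cand[ok])[seq_len(min(n, length(cen) + sum(ok)))]
    }
    cen <- sort(cen)
    m <- stats::rlnorm(n, meanlog = log(15), sdlog = 0.8)
    data.frame(centroid = cen, mean = m, sd = 0.35 * m)
  })
}

#' Build a simulation configuration
#'
#' Defaults reproduce the study conditions the analysis assumes: a 50/50
#' training-style cohort over 800-10000 Da, the calibrated discriminating-peak
#' catalogue ([defaultDiscriminatingPeaks()]), 120 background peaks, a
#' decaying-exponential baseline, iid Gaussian intensity noise, log-normal
#' per-spectrum total-ion-current spread, a small per-spectrum affine m/z
#' calibration error, and a 2.4% rate of low-quality (unclassifiable) spectra.
#'
#' @param nMutant,nWild cohort sizes.
#' @param mzRange,gridStep acquisition grid (Da).
#' @param discriminatingPeaks,backgroundPeaks peak catalogues (see
#'   [defaultDiscriminatingPeaks()], [defaultBackgroundPeaks()]).
#' @param resolution relative Gaussian peak width (sigma = centroid * resolution).
#' @param baselineAmplitude,baselineDecay,baselineConstant baseline model.
#' @param noiseSigma iid intensity noise SD (raw units).
#' @param ticVariation sdlog of the per-spectrum multiplicative factor.
#' @param calibrationScaleMax,calibrationOffsetMax affine distortion bounds.
#' @param invalidRate probability a spectrum is rendered low-quality.
#' @param seed study seed.
#' @return a [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nMutant = 50L, nWild = 50L,
                             mzRange = c(800, 10000), gridStep = 0.25,
                             discriminatingPeaks = defaultDiscriminatingPeaks(),
                             backgroundPeaks = defaultBackgroundPeaks(mzRange = mzRange),
                             resolution = 1 / 3000,
                             baselineAmplitude = 20, baselineDecay = 1500,
                             baselineConstant = 1, noiseSigma = 0.5,
                             ticVariation = 0.15,
                             calibrationScaleMax = 3e-4,
                             calibrationOffsetMax = 0.5,
                             invalidRate = 0.024, seed = 1L) {
  new("SimulationConfig", nMutant = as.integer(nMutant), nWild = as.integer(nWild),
      mzRange = as.numeric(mzRange), gridStep = as.numeric(gridStep),
      discriminatingPeaks = discriminatingPeaks, backgroundPeaks = backgroundPeaks,
      resolution = resolution, baselineAmplitude = baselineAmplitude,
      baselineDecay = baselineDecay, baselineConstant = baselineConstant,
      noiseSigma = noiseSigma, ticVariation = ticVariation,
      calibrationScaleMax = calibrationScaleMax,
      calibrationOffsetMax = calibrationOffsetMax,
      invalidRate = invalidRate, seed = as.integer(seed))
}

#' Build clinical-outcome parameters
#'
#' Defaults are calibrated to the reported EGFR-TKI outcomes: objective
#' response 59.6% vs 8.8%, disease control 87.2% vs 35.3%, exponential PFS
#' medians 10.0 vs 2.3 months and OS medians 29.0 vs 28.0 months for the
#' mutant vs wild classes, with administrative censoring at 40 months (the
#' maximum reported follow-up). Complete response is generated with
#' probability zero (its observed count is zero).
#'
#' @param pObjectiveResponse,pDiseaseControl,pfsMedian,osMedian named numeric
#'   vectors with elements `mutant` and `wild`.
#' @param censorHorizon months.
#' @param seed integer.
#' @return an [OutcomeParams-class] object.
#' @export
outcomeParams <- function(pObjectiveResponse = c(mutant = 0.596, wild = 0.088),
                          pDiseaseControl = c(mutant = 0.872, wild = 0.353),
                          pfsMedian = c(mutant = 10.0, wild = 2.3),
                          osMedian = c(mutant = 29.0, wild = 28.0),
                          censorHorizon = 40, seed = 1L) {
  new("OutcomeParams", pObjectiveResponse = pObjectiveResponse,
      pDiseaseControl = pDiseaseControl, pfsMedian = pfsMedian,
      osMedian = osMedian, censorHorizon = censorHorizon,
      seed = as.integer(seed))
}

#' Draw peak areas from a zero-truncated normal
#'
#' Peak areas are drawn from normal distributions with the configured
#' class-conditional mean and SD, truncated at zero (areas are nonnegative;
#' only mean +/- SD is published, so the family is a modelling choice).
#' Rejection sampling; deterministic given the RNG state.
#'
#' @param n number of draws.
#' @param mean,sd untruncated normal parameters; `sd > 0`.
#' @return numeric vector of nonnegative areas.
#' @export
drawPeakAreas <- function(n, mean, sd) {
  stopifnot(sd > 0, n >= 0)
  out <- stats::rnorm(n, mean, sd)
  bad <- out < 0
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < 0
  }
  out
}

# Gaussian peak contributions accumulated on a grid; each peak only evaluated
# within +/- 8 sigma of its (possibly distorted) centroid.
.addPeaks <- function(grid, intensity, centroids, areas, sigmas) {
  step <- grid[2] - grid[1]
  n <- length(grid)
  for (j in seq_along(centroids)) {
    if (areas[j] <= 0) next
    lo <- max(1L, floor((centroids[j] - 8 * sigmas[j] - grid[1]) / step) + 1L)
    hi <- min(n, ceiling((centroids[j] + 8 * sigmas[j] - grid[1]) / step) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    intensity[idx] <- intensity[idx] +
      areas[j] * stats::dnorm(grid[idx], centroids[j], sigmas[j])
  }
  intensity
}

#' Simulate one raw profile spectrum
#'
#' Intensities are baseline + sum of Gaussian peaks + iid Gaussian noise, the
#' whole signal scaled by a per-spectrum log-normal total-ion-current factor
#' and clipped at zero. Discriminating peak areas are drawn from the
#' class-conditional zero-truncated normals; background peak areas are
#' class-independent. Peak positions carry a per-spectrum affine m/z
#' distortion (recorded in the metadata); the grid itself is undistorted.
#' Low-quality spectra have every peak amplitude multiplied by 0.02, which
#' collapses the signal below the detection SNR.
#'
#' @param patientClass "mutant" or "wild".
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed for this spectrum (defaults to the config seed).
#' @param sampleIdLabel sample identifier.
#' @param lowQuality logical; render the spectrum unclassifiable.
#' @return a [MassSpectrum-class] with metadata fields `trueClass`, `seed`,
#'   `calScale`, `calOffset`, `ticFactor`, `lowQuality`.
#' @export
simulateSpectrum <- function(patientClass = c("mutant", "wild"), config,
                             seed = config@seed, sampleIdLabel = "sim",
                             lowQuality = FALSE) {
  patientClass <- match.arg(patientClass)
  validObject(config)
  if (config@gridStep <= 0) stop("configuration error: gridStep must be > 0")
  dp <- config@discriminatingPeaks; bp <- config@backgroundPeaks
  if (nrow(dp) + nrow(bp) == 0L) stop("configuration error: empty peak catalogue")
  grid <- seq(config@mzRange[1], config@mzRange[2], by = config@gridStep)
  withSeed(seed, {
    calScale <- 1 + stats::runif(1, -config@calibrationScaleMax, config@calibrationScaleMax)
    calOffset <- stats::runif(1, -config@calibrationOffsetMax, config@calibrationOffsetMax)
    if (nrow(dp)) {
      mu <- if (patientClass == "mutant") dp$meanMutant else dp$meanWild
      sg <- if (patientClass == "mutant") dp$sdMutant else dp$sdWild
      areasD <- vapply(seq_len(nrow(dp)), function(j) drawPeakAreas(1L, mu[j], sg[j]),
                       numeric(1))
    } else areasD <- numeric(0)
    areasB <- if (nrow(bp))
      vapply(seq_len(nrow(bp)), function(j) drawPeakAreas(1L, bp$mean[j], bp$sd[j]),
             numeric(1)) else numeric(0)
    amp <- if (lowQuality) 0.02 else 1
    cen <- c(dp$centroid, bp$centroid)
    areas <- amp * c(areasD, areasB)
    sigmas <- cen * config@resolution
    base <- config@baselineAmplitude *
      exp(-(grid - config@mzRange[1]) / config@baselineDecay) + config@baselineConstant
    y <- .addPeaks(grid, base, calScale * cen + calOffset, areas, sigmas)
    if (config@noiseSigma > 0) y <- y + stats::rnorm(length(grid), 0, config@noiseSigma)
    ticFactor <- if (config@ticVariation > 0) exp(stats::rnorm(1, 0, config@ticVariation)) else 1
    y <- pmax(y * ticFactor, 0)
    MassSpectrum(sampleIdLabel, grid, y,
                 metadata = list(trueClass = patientClass, seed = seed,
                                 calScale = calScale, calOffset = calOffset,
                                 ticFactor = ticFactor, lowQuality = lowQuality,
                                 trueAreas = stats::setNames(areas / amp,
                                                             sprintf("%.2f", cen))))
  })
}

#' Simulate a cohort of raw spectra
#'
#' Generates `nMutant + nWild` spectra with recorded true labels. A fraction
#' of spectra, drawn Bernoulli(`invalidRate`) from a cohort-level substream,
#' is rendered low-quality (peak amplitudes suppressed below detection). Each
#' patient has their own RNG substream spawned from the config seed, so any
#' single spectrum can be regenerated in isolation.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `spectra` (list of [MassSpectrum-class]) and `metadata`
#'   (data.frame: sample_id, true_class, invalid_flag, seed).
#' @export
simulateCohort <- function(config) {
  validObject(config)
  n <- config@nMutant + config@nWild
  if (n < 1L) stop("configuration error: empty cohort")
  classes <- c(rep("mutant", config@nMutant), rep("wild", config@nWild))
  ids <- sprintf("S%03d", seq_len(n))
  flags <- withSeed(childSeed(config@seed, 0L),
                    stats::runif(n) < config@invalidRate)
  seeds <- vapply(seq_len(n), function(i) childSeed(config@seed, i), integer(1))
  spectra <- lapply(seq_len(n), function(i)
    simulateSpectrum(classes[i], config, seed = seeds[i], sampleIdLabel = ids[i],
                     lowQuality = flags[i]))
  list(spectra = spectra,
       metadata = data.frame(sample_id = ids, true_class = classes,
                             invalid_flag = flags, seed = seeds,
                             stringsAsFactors = FALSE))
}

#' Attach simulated clinical outcomes to a cohort
#'
#' RECIST response is drawn per patient among PR/SD/PD (CR has probability
#' zero) from the true class's objective-response and disease-control
#' probabilities; PFS and OS are exponential with the class's median
#' (rate = log(2)/median) and right-censored at the follow-up horizon.
#' Treatment line is carried as a covariate and never analyzed.
#'
#' @param metadata cohort metadata with a `true_class` column.
#' @param params an [OutcomeParams-class].
#' @return the metadata with added columns tki_line, response, pfs_months,
#'   pfs_event, os_months, os_event.
#' @export
simulateOutcomes <- function(metadata, params) {
  validObject(params)
  if (!"true_class" %in% names(metadata) || anyNA(metadata$true_class))
    stop("every patient must have a true class")
  if (any(params@pDiseaseControl[c("mutant", "wild")] <
          params@pObjectiveResponse[c("mutant", "wild")]))
    stop("configuration error: disease-control probability below objective-response")
  n <- nrow(metadata)
  lineProb <- list(mutant = c(0.62, 0.32, 0.06), wild = c(0.24, 0.50, 0.26))
  res <- lapply(seq_len(n), function(i) {
    cl <- metadata$true_class[i]
    withSeed(childSeed(params@seed, i + 1000000L), {
      pOR <- params@pObjectiveResponse[[cl]]; pDC <- params@pDiseaseControl[[cl]]
      resp <- sample(c("PR", "SD", "PD"), 1L, prob = c(pOR, pDC - pOR, 1 - pDC))
      pfs <- stats::rexp(1, log(2) / params@pfsMedian[[cl]])
      os <- stats::rexp(1, log(2) / params@osMedian[[cl]])
      line <- sample(c("first", "second", "third_plus"), 1L, prob = lineProb[[cl]])
      data.frame(tki_line = line, response = resp,
                 pfs_months = min(pfs, params@censorHorizon),
                 pfs_event = as.integer(pfs <= params@censorHorizon),
                 os_months = min(os, params@censorHorizon),
                 os_event = as.integer(os <= params@censorHorizon),
                 stringsAsFactors = FALSE)
    })
  })
  cbind(metadata, do.call(rbind, res))
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simulationConfig()]; peak catalogues may be
#' given as lists of rows or omitted to keep the calibrated defaults.
#'
#' @param path YAML file.
#' @return a [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  scal <- c("nMutant", "nWild", "gridStep", "resolution", "baselineAmplitude",
            "baselineDecay", "baselineConstant", "noiseSigma", "ticVariation",
            "calibrationScaleMax", "calibrationOffsetMax", "invalidRate", "seed")
  for (k in scal) if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$mzRange)) args$mzRange <- as.numeric(unlist(y$mzRange))
  for (k in c("discriminatingPeaks", "backgroundPeaks"))
    if (!is.null(y[[k]]))
      args[[k]] <- do.call(rbind, lapply(y[[k]], as.data.frame))
  do.call(simulationConfig, args)
}
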