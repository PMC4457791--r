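#' Configuration of a full simulated study
#'
#' Bundles the generator, preprocessing and classifier settings of an
#' end-to-end run: a 50/50 training cohort (no low-quality spectra, as all
#' training spectra entered the original analysis) and a 52/71 validation
#' cohort with a 2.4% unclassifiable rate, both drawn from the calibrated
#' peak catalogue; candidate models GA-3/GA-5/GA-7, the prototype classifier
#' and the quick classifier, compared by 20% x 10 repeated random-split
#' cross-validation.
#'
#' @param seed study seed; every stage derives its stream from it.
#' @param nTrainMutant,nTrainWild,nValMutant,nValWild cohort sizes.
#' @param invalidRateValidation low-quality rate in the validation cohort.
#' @param gaSettings see [gaParams()].
#' @param kGrid odd neighbour counts for the GA-kNN candidates.
#' @param outcome an [OutcomeParams-class].
#' @param ... further arguments passed to [simulationConfig()] (shared by
#'   both cohorts).
#' @return list of settings consumed by [runFullStudy()].
#' @export
studyConfig <- function(seed = 1L, nTrainMutant = 50L, nTrainWild = 50L,
                        nValMutant = 52L, nValWild = 71L,
                        invalidRateValidation = 0.024,
                        gaSettings = gaParams(), kGrid = c(3L, 5L, 7L),
                        outcome = outcomeParams(seed = childSeed(seed, 5L)),
                        ...) {
  list(seed = as.integer(seed),
       training = simulationConfig(nMutant = nTrainMutant, nWild = nTrainWild,
                                   invalidRate = 0,
                                   seed = childSeed(seed, 3L), ...),
       validation = simulationConfig(nMutant = nValMutant, nWild = nValWild,
                                     invalidRate = invalidRateValidation,
                                     seed = childSeed(seed, 4L), ...),
       outcome = outcome, gaSettings = gaSettings, kGrid = kGrid)
}

.digestFiles <- function(paths) {
  ok <- file.exists(paths)
  out <- rep(NA_character_, length(paths))
  out[ok] <- unname(tools::md5sum(paths[ok]))
  stats::setNames(out, basename(paths))
}

#' Run the full simulated study end to end
#'
#' Simulates the training and validation cohorts, preprocesses each into a
#' feature matrix, computes differential peaks on the training group only,
#' trains the candidate classifiers (GA-kNN over `kGrid`, prototype, quick
#' classifier) on the training group only, selects the best model by
#' cross-validation percentage (ties broken toward fewer peaks), classifies
#' the validation cohort blind — the validation truth labels are never
#' passed to any stage before the final evaluation — and evaluates clinical
#' concordance, response and survival.
#'
#' @param config from [studyConfig()].
#' @param outDir directory for stage outputs and the run manifest; created
#'   if missing. `NULL` keeps everything in memory.
#' @return list: manifest (settings, seeds, model table, file digests),
#'   diffPeaks, models (per candidate: model + CVResult), bestModel,
#'   predictions, evaluation, trainingMatrix, validationMatrix.
#' @export
runFullStudy <- function(config = studyConfig(), outDir = NULL) {
  stageFiles <- character(0)
  emit <- function(x, name, writer = writeTable) {
    if (is.null(outDir)) return(invisible(NULL))
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    p <- file.path(outDir, name)
    writer(x, p)
    stageFiles <<- c(stageFiles, p)
    invisible(p)
  }
  if (config$training@nMutant < 1L || config$training@nWild < 1L ||
      config$validation@nMutant < 1L || config$validation@nWild < 1L)
    stop("configuration error: both classes need at least one patient per cohort")
  # --- simulate ---
  train <- simulateCohort(config$training)
  val <- simulateCohort(config$validation)
  valTruth <- val$metadata$true_class      # withheld until evaluation
  val$metadata$true_class <- NULL
  emit(train$metadata, "training_metadata.csv")
  # --- preprocess ---
  mzr <- config$training@mzRange
  fmTrain <- buildFeatureMatrix(train$spectra, mzRange = mzr)
  fmVal <- buildFeatureMatrix(val$spectra, mzRange = mzr,
                              peaks = peakDefinitions(fmTrain))
  emit(NULL, "training_features.csv",
       function(x, p) writeFeatureMatrix(fmTrain, p,
                                         file.path(outDir, "training_peaks.csv")))
  # --- differential peaks (training only) ---
  dp <- differentialPeaks(fmTrain, train$metadata$true_class)
  emit(dp, "differential_peaks.csv")
  # --- classifiers (training only) ---
  yTrain <- train$metadata$true_class
  models <- list()
  for (k in config$kGrid) {
    g <- trainGAKNN(fmTrain, yTrain, k = k, params = config$gaSettings,
                    seed = childSeed(config$seed, 10L + k))
    models[[sprintf("GA-%d", k)]] <- g
  }
  snn <- trainSNN(fmTrain, yTrain, seed = childSeed(config$seed, 20L))
  models[["SNN"]] <- list(
    model = snn,
    cv = crossValidate(function(X, y) trainSNN(X, y,
                                               seed = childSeed(config$seed, 21L)),
                       fmTrain, yTrain, seed = childSeed(config$seed, 22L)))
  qc <- trainQC(fmTrain, yTrain)
  models[["QC"]] <- list(
    model = qc,
    cv = crossValidate(function(X, y) trainQC(X, y), fmTrain, yTrain,
                       seed = childSeed(config$seed, 23L)))
  cvTable <- data.frame(
    name = names(models),
    crossValidationPct = vapply(models, function(m) m$cv@crossValidationPct,
                                numeric(1)),
    recognitionPct = vapply(models, function(m) m$cv@recognitionPct, numeric(1)),
    nPeaks = vapply(models, function(m) length(m$model@selectedPeaks),
                    numeric(1)), row.names = NULL)
  emit(cvTable, "model_comparison.csv")
  # best model: highest cross-validation, ties toward fewer peaks
  o <- order(-cvTable$crossValidationPct, cvTable$nPeaks)
  bestName <- cvTable$name[o[1]]
  best <- models[[bestName]]$model
  emit(best, "best_model.json", function(x, p) saveModel(x, p))
  # --- blind classification of the validation cohort ---
  pred <- classifySamples(best, fmVal)
  predTab <- data.frame(sample_id = colnames(fmVal), predicted = unname(pred))
  emit(predTab, "validation_predictions.csv")
  # --- clinical evaluation (truth revealed here) ---
  valMeta <- data.frame(sample_id = val$metadata$sample_id,
                        true_class = valTruth,
                        invalid_flag = val$metadata$invalid_flag)
  valMeta <- simulateOutcomes(valMeta, config$outcome)
  records <- merge(valMeta, predTab, by = "sample_id")
  records$truth <- records$true_class
  evalRes <- clinicalEvaluation(records)
  emit(records, "validation_records.csv")
  manifest <- list(
    seed = config$seed,
    cohortSizes = c(trainMutant = config$training@nMutant,
                    trainWild = config$training@nWild,
                    valMutant = config$validation@nMutant,
                    valWild = config$validation@nWild),
    bestModel = bestName,
    modelTable = cvTable,
    nDetectedPeaksTraining = nrow(peakDefinitions(fmTrain)),
    fileDigests = .digestFiles(stageFiles),
    timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(outDir)) {
    mPath <- file.path(outDir, "run_manifest.json")
    writeLines(jsonlite::toJSON(manifest[setdiff(names(manifest), "timestamp")],
                                digits = NA, auto_unbox = TRUE, pretty = TRUE),
               mPath)
  }
  list(manifest = manifest, diffPeaks = dp, models = models,
       bestModel = best, bestModelName = bestName, predictions = predTab,
       evaluation = evalRes, trainingMatrix = fmTrain, validationMatrix = fmVal,
       records = records)
}
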