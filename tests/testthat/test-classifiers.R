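# A separable two-class feature matrix with centroid-named columns.
sepData <- function(n = 20, p = 4, shift = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * p), ncol = p)
  X[seq_len(n), 1:2] <- X[seq_len(n), 1:2] + shift
  colnames(X) <- sprintf("mz_%d", 1000 + seq_len(p) * 250)
  list(X = X, y = rep(c("mutant", "wild"), each = n))
}

test_that("k-NN prediction agrees exactly with a brute-force oracle", {
  set.seed(90)
  for (r in 1:8) {
    tr <- matrix(rnorm(30 * 5), ncol = 5)
    te <- matrix(rnorm(12 * 5), ncol = 5)
    y <- sample(c("mutant", "wild"), 30, replace = TRUE)
    for (k in c(1, 3, 7))
      expect_identical(knnPredict(tr, y, te, k), knnOracle(tr, y, te, k))
  }
})

test_that("an even-k vote tie falls back to the conservative label", {
  tr <- matrix(c(4, 7), ncol = 1)   # one neighbour per class
  te <- matrix(5, ncol = 1)
  expect_identical(knnPredict(tr, c("mutant", "wild"), te, k = 2), "wild")
})

test_that("the quick classifier separates, weights by evidence and persists", {
  d <- sepData(seed = 91)
  m <- trainQC(d$X, d$y)
  expect_s4_class(m, "ClassifierModel")
  expect_identical(m@kind, "QC")
  expect_identical(unname(classifySamples(m, d$X)), d$y)
  cv <- crossValidate(function(X, y) trainQC(X, y), d$X, d$y, seed = 92)
  expect_equal(recognitionPct(cv), 100)
  # constant peaks are skipped with a warning
  Xc <- cbind(d$X, mz_9000 = rep(5, nrow(d$X)))
  expect_warning(mc <- trainQC(Xc, d$y), "constant")
  expect_false(9000 %in% selectedPeaks(mc))
})

test_that("label-independent features give chance-level cross-validation", {
  set.seed(93)
  X <- matrix(rnorm(40 * 6), ncol = 6)
  colnames(X) <- sprintf("mz_%d", 1:6 * 400 + 800)
  y <- rep(c("mutant", "wild"), each = 20)
  cvq <- crossValidate(function(Xt, yt) trainQC(Xt, yt), X, y, seed = 94)
  expect_gte(crossValidationPct(cvq), 35)
  expect_lte(crossValidationPct(cvq), 65)
})

test_that("the prototype classifier learns separable classes and sits at class means", {
  d <- sepData(n = 30, seed = 95)
  m <- trainSNN(d$X, d$y, seed = 96)
  expect_gte(mean(classifySamples(m, d$X) == d$y) * 100, 95)
  # one prototype per class on symmetric data converges near the class means
  m1 <- trainSNN(d$X, d$y, prototypesPerClass = 1L, seed = 97)
  Z <- scale(d$X, center = m1@scaling$center, scale = m1@scaling$scale)
  for (cl in c("mutant", "wild")) {
    proto <- m1@decisionData$prototypes[m1@decisionData$protoClass == cl, ]
    mu <- colMeans(Z[d$y == cl, , drop = FALSE])
    expect_lt(sqrt(sum((proto - mu)^2)), 1.5)
  }
  # label shuffling drives cross-validation toward chance
  set.seed(98)
  yShuf <- sample(d$y)
  cvs <- crossValidate(function(X, y) trainSNN(X, y, seed = 99),
                       d$X, yShuf, seed = 100)
  expect_gte(crossValidationPct(cvs), 25)
  expect_lte(crossValidationPct(cvs), 75)
})

test_that("the GA recovers planted informative peaks across seeds", {
  recovered <- 0L
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 20
    X <- matrix(rnorm(2 * n * 52), ncol = 52)
    X[seq_len(n), 1] <- X[seq_len(n), 1] + 3.5
    X[seq_len(n), 2] <- X[seq_len(n), 2] - 3.5
    colnames(X) <- sprintf("mz_%d", 900 + seq_len(52) * 150)
    y <- rep(c("mutant", "wild"), each = n)
    fit <- trainGAKNN(X, y, k = 3, seed = 200 + s,
                      params = gaParams(populationSize = 32L, generations = 20L))
    sel <- selectedPeaks(fit$model)
    recovered <- recovered + (1050 %in% sel && 1200 %in% sel)
  }
  expect_gte(recovered, 9L)
})

test_that("GA elite fitness never decreases and the search is reproducible", {
  d <- sepData(n = 15, p = 10, shift = 2, seed = 201)
  f1 <- trainGAKNN(d$X, d$y, k = 3, seed = 7,
                   params = gaParams(populationSize = 16L, generations = 12L))
  expect_true(all(diff(f1$fitnessTrace) >= -1e-12))
  f2 <- trainGAKNN(d$X, d$y, k = 3, seed = 7,
                   params = gaParams(populationSize = 16L, generations = 12L))
  expect_identical(selectedPeaks(f1$model), selectedPeaks(f2$model))
  expect_equal(crossValidationPct(f1$cv), crossValidationPct(f2$cv))
  # population 1 / generations 0 degenerates to a random subset but still runs
  f0 <- trainGAKNN(d$X, d$y, k = 3, seed = 8,
                   params = gaParams(populationSize = 1L, generations = 0L))
  expect_s4_class(f0$model, "ClassifierModel")
  # a subset-size range beyond the peak count is refused
  expect_error(trainGAKNN(d$X, d$y, k = 3, seed = 9,
                          params = gaParams(subsetSizeRange = c(11L, 12L))),
               "subset-size")
  expect_error(trainGAKNN(d$X, d$y, k = 4, seed = 9), "odd")
})

test_that("standardization makes classification invariant to per-peak rescaling", {
  d <- sepData(seed = 202)
  te <- matrix(rnorm(20 * 4), ncol = 4); colnames(te) <- colnames(d$X)
  scale <- c(100, 0.01, 7, 3); offset <- c(5, -2, 0, 40)
  Xr <- sweep(sweep(d$X, 2, scale, "*"), 2, offset, "+")
  ter <- sweep(sweep(te, 2, scale, "*"), 2, offset, "+")
  colnames(Xr) <- colnames(ter) <- colnames(d$X)
  for (trainer in list(
    function(X, y) trainQC(X, y),
    function(X, y) trainGAKNN(X, y, k = 3, seed = 1,
                              params = gaParams(populationSize = 8L,
                                                generations = 4L))$model)) {
    m <- trainer(d$X, d$y); mr <- trainer(Xr, d$y)
    expect_identical(classifySamples(m, te), classifySamples(mr, ter))
  }
})

test_that("repeated random-split cross-validation is stratified, optimistic and reproducible", {
  d <- sepData(seed = 203)
  cv1 <- crossValidate(function(X, y) trainQC(X, y), d$X, d$y, seed = 11)
  expect_equal(crossValidationPct(cv1), 100)
  expect_equal(recognitionPct(cv1), 100)
  cv2 <- crossValidate(function(X, y) trainQC(X, y), d$X, d$y, seed = 11)
  expect_identical(cv1@perIteration, cv2@perIteration)
  expect_length(cv1@perIteration, 10L)
  expect_error(crossValidate(function(X, y) trainQC(X, y), d$X, d$y,
                             stratified = FALSE), "stratified|unstratified")
  # recognition >= cross-validation on average under the null
  set.seed(204)
  gap <- replicate(5, {
    X <- matrix(rnorm(30 * 5), ncol = 5)
    colnames(X) <- sprintf("mz_%d", 1:5 * 300 + 900)
    y <- rep(c("mutant", "wild"), each = 15)
    cv <- crossValidate(function(Xt, yt) trainQC(Xt, yt), X, y,
                        seed = sample.int(1e6, 1))
    recognitionPct(cv) - crossValidationPct(cv)
  })
  expect_gt(mean(gap), 0)
})

test_that("classification handles QC flags, determinism and missing columns", {
  d <- sepData(seed = 205)
  m <- trainQC(d$X, d$y)
  probe <- d$X[1, , drop = FALSE]
  expect_identical(classifySamples(m, probe), classifySamples(m, probe))
  # a sample placed at the mutant training centroid is labeled mutant
  centroidRow <- matrix(colMeans(d$X[d$y == "mutant", ]), nrow = 1,
                        dimnames = list(NULL, colnames(d$X)))
  expect_identical(unname(classifySamples(m, centroidRow)), "mutant")
  # missing model peak column: an error, not 'unclassifiable'
  expect_error(classifySamples(m, d$X[, 1:2]), "missing model peak")
})

test_that("invalid spectra in a feature matrix come back unclassifiable", {
  cfg <- simulationConfig(nMutant = 6L, nWild = 6L, invalidRate = 0,
                          mzRange = c(3000, 5000), seed = 206L)
  coh <- simulateCohort(cfg)
  lq <- simulateSpectrum("wild", cfg, seed = 207L, sampleIdLabel = "LQ",
                         lowQuality = TRUE)
  fm <- buildFeatureMatrix(c(coh$spectra, list(lq)))
  m <- trainQC(fm[, qcFlags(fm) == "ok"], coh$metadata$true_class)
  pred <- classifySamples(m, fm)
  expect_identical(unname(pred["LQ"]), "unclassifiable")
  expect_true(all(pred[names(pred) != "LQ"] %in% c("mutant", "wild")))
})

test_that("models survive a save/load round-trip and reject corrupt files", {
  d <- sepData(seed = 208)
  te <- matrix(rnorm(100 * 4), ncol = 4); colnames(te) <- colnames(d$X)
  models <- list(
    trainQC(d$X, d$y),
    trainSNN(d$X, d$y, seed = 1),
    trainGAKNN(d$X, d$y, k = 3, seed = 2,
               params = gaParams(populationSize = 8L, generations = 4L))$model)
  for (m in models) {
    path <- withr::local_tempfile(fileext = ".json")
    saveModel(m, path)
    m2 <- loadModel(path)
    expect_identical(classifySamples(m2, te), classifySamples(m, te))
  }
  # a five-peak model persists exactly five centroids
  m5 <- trainGAKNN(d$X, d$y, k = 3, seed = 3,
                   params = gaParams(populationSize = 8L, generations = 4L,
                                     subsetSizeRange = c(4L, 4L)))$model
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(m5, path)
  expect_length(loadModel(path)@selectedPeaks, 4L)
  # truncation and tampering are both load errors
  full <- readLines(path)
  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(head(full, length(full) %/% 2), trunc)
  expect_error(loadModel(trunc), "load error")
  tampered <- withr::local_tempfile(fileext = ".json")
  writeLines(sub("\"k\": 3", "\"k\": 1", full), tampered)
  expect_error(loadModel(tampered), "checksum")
})
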