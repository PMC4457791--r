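# ---- shared helpers -------------------------------------------------------

# Accept a PeakFeatureMatrix (invalid samples dropped) or a samples x features
# matrix whose colnames parse as centroids. Returns samples x peaks X, labels,
# centroids, and (when available) the peak integration bounds.
.asTraining <- function(fm, labels) {
  if (is(fm, "PeakFeatureMatrix")) {
    keep <- qcFlags(fm) == "ok"
    X <- t(peakAreas(fm)[, keep, drop = FALSE])
    labels <- labels[keep]
    pd <- peakDefinitions(fm)
    centroids <- pd$centroid
    bounds <- pd[, c("centroid", "leftBound", "rightBound"), drop = FALSE]
  } else {
    X <- as.matrix(fm)
    centroids <- suppressWarnings(as.numeric(sub("^mz_", "", colnames(X))))
    if (anyNA(centroids)) centroids <- seq_len(ncol(X))
    bounds <- NULL
  }
  y <- as.character(labels)
  if (length(y) != nrow(X)) stop("labels do not match the samples")
  if (length(unique(y)) != 2L) stop("exactly two classes are required")
  counts <- table(y)
  if (any(counts < 3L)) stop("each class needs at least 3 samples")
  colnames(X) <- sprintf("mz_%.6g", centroids)
  list(X = X, y = y, centroids = centroids, bounds = bounds)
}

.classOrder <- function(y) {
  cls <- unique(y)
  c(intersect(c("mutant", "wild"), cls), setdiff(cls, c("mutant", "wild")))
}

.scaleCols <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

.applyScale <- function(X, sc) sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")

#' k-nearest-neighbour prediction with standardized Euclidean distance
#'
#' Majority vote among the `k` nearest training exemplars. Inputs are
#' expected already on a common (standardized) scale. With two classes and
#' odd `k` a vote tie cannot occur; if one does (even `k`), it is broken
#' toward `tieBreak` — conservatively "wild", i.e. against recommending
#' treatment.
#'
#' @param trainX,trainY training exemplars (samples x features) and labels.
#' @param testX query samples (samples x features).
#' @param k number of neighbours.
#' @param tieBreak label awarded on a vote tie.
#' @return character vector of predicted labels.
#' @export
knnPredict <- function(trainX, trainY, testX, k, tieBreak = "wild") {
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  stopifnot(k >= 1L, nrow(trainX) >= k, ncol(trainX) == ncol(testX))
  trainY <- as.character(trainY)
  lev <- unique(trainY)
  if (length(lev) > 2L) stop("two-class classification only")
  yi <- match(trainY, lev)
  tie <- if (tieBreak %in% lev) match(tieBreak, lev) else 1L
  pred <- .knnVote(trainX, yi, testX, as.integer(k), tie)
  lev[pred]
}

# ---- quick classifier -----------------------------------------------------

#' Train a quick classifier (univariate weighted voting)
#'
#' Peaks are ranked by Welch p-value and the top `maxPeaks` retained;
#' constant (zero-variance) peaks are skipped with a warning. Classification
#' is a weighted vote: each peak votes for the class whose (standardized)
#' training mean is nearer, with weight -log10(p); ties go to "wild".
#'
#' @param fm a [PeakFeatureMatrix-class] or samples x features matrix.
#' @param labels class labels per sample.
#' @param maxPeaks maximum number of peaks retained.
#' @return a [ClassifierModel-class] of kind "QC".
#' @export
trainQC <- function(fm, labels, maxPeaks = 25L) {
  d <- .asTraining(fm, labels)
  cls <- .classOrder(d$y)
  const <- apply(d$X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sum(const), " constant peak(s) skipped")
    d$X <- d$X[, !const, drop = FALSE]; d$centroids <- d$centroids[!const]
  }
  if (!ncol(d$X)) stop("no usable peaks")
  p <- vapply(seq_len(ncol(d$X)), function(j) {
    a <- d$X[d$y == cls[1], j]; b <- d$X[d$y == cls[2], j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  sel <- order(p)[seq_len(min(maxPeaks, ncol(d$X)))]
  sc <- .scaleCols(d$X[, sel, drop = FALSE])
  Z <- .applyScale(d$X[, sel, drop = FALSE], sc)
  classMeans <- rbind(colMeans(Z[d$y == cls[1], , drop = FALSE]),
                      colMeans(Z[d$y == cls[2], , drop = FALSE]))
  rownames(classMeans) <- cls
  new("ClassifierModel", kind = "QC", selectedPeaks = d$centroids[sel],
      decisionData = list(weights = -log10(pmax(p[sel], 1e-300)),
                          classMeans = classMeans,
                          bounds = .selBounds(d$bounds, d$centroids[sel])),
      scaling = sc, classLabels = cls)
}

.selBounds <- function(bounds, centroids) {
  if (is.null(bounds)) return(NULL)
  idx <- match(centroids, bounds$centroid)
  bounds[idx, , drop = FALSE]
}

# ---- supervised prototype classifier (LVQ) --------------------------------

#' Train a supervised prototype classifier (LVQ1-style)
#'
#' Prototypes are initialized at the class means plus a small seeded jitter
#' and trained by LVQ1: the nearest prototype is attracted to a same-class
#' sample and repelled from an other-class sample, with a linearly decaying
#' learning rate. Classification is by nearest prototype in standardized
#' space. If prototypes are still moving materially after the last epoch the
#' model is returned with a `converged = FALSE` flag and a warning.
#'
#' @param fm a [PeakFeatureMatrix-class] or samples x features matrix.
#' @param labels class labels.
#' @param prototypesPerClass prototypes per class.
#' @param epochs training epochs.
#' @param alphaStart initial learning rate.
#' @param seed RNG seed for initialization and presentation order.
#' @return a [ClassifierModel-class] of kind "SNN".
#' @export
trainSNN <- function(fm, labels, prototypesPerClass = 3L, epochs = 40L,
                     alphaStart = 0.3, seed = 1L) {
  d <- .asTraining(fm, labels)
  cls <- .classOrder(d$y)
  sc <- .scaleCols(d$X)
  Z <- .applyScale(d$X, sc)
  withSeed(seed, {
    protos <- do.call(rbind, lapply(cls, function(cl) {
      mu <- colMeans(Z[d$y == cl, , drop = FALSE])
      t(replicate(prototypesPerClass, mu + stats::rnorm(length(mu), 0, 0.1)))
    }))
    protoClass <- rep(cls, each = prototypesPerClass)
    n <- nrow(Z)
    total <- epochs * n
    tstep <- 0L
    lastShift <- Inf
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      shift <- 0
      for (i in ord) {
        tstep <- tstep + 1L
        alpha <- alphaStart * (1 - tstep / total)
        dd <- rowSums(sweep(protos, 2, Z[i, ])^2)
        w <- which.min(dd)
        dir <- if (protoClass[w] == d$y[i]) 1 else -1
        delta <- alpha * dir * (Z[i, ] - protos[w, ])
        protos[w, ] <- protos[w, ] + delta
        shift <- shift + sum(abs(delta))
      }
      lastShift <- shift
    }
    # converged when the average per-coordinate movement in the last epoch is
    # small on the z-score scale
    converged <- lastShift / (n * ncol(Z)) <= 0.01
    if (!converged) warning("prototype classifier did not converge within ",
                            epochs, " epochs")
    widths <- vapply(cls, function(cl)
      sum(diag(stats::cov(Z[d$y == cl, , drop = FALSE]))), numeric(1))
    new("ClassifierModel", kind = "SNN", selectedPeaks = d$centroids,
        decisionData = list(prototypes = protos, protoClass = protoClass,
                            widths = widths, converged = converged,
                            bounds = .selBounds(d$bounds, d$centroids)),
        scaling = sc, classLabels = cls)
  })
}

# ---- GA-kNN ---------------------------------------------------------------

#' Genetic-algorithm parameters for GA-kNN feature selection
#'
#' @param populationSize,generations GA size.
#' @param crossoverRate probability a pair undergoes uniform set-crossover.
#' @param mutationRate per-slot probability of replacing a selected peak by a
#'   random other peak.
#' @param elitism number of elites copied unchanged.
#' @param subsetSizeRange allowed subset sizes.
#' @param fitnessFolds folds of the internal stratified CV used as fitness.
#' @return list of GA settings.
#' @export
gaParams <- function(populationSize = 64L, generations = 40L,
                     crossoverRate = 0.7, mutationRate = 0.05, elitism = 1L,
                     subsetSizeRange = c(3L, 8L), fitnessFolds = 5L) {
  list(populationSize = as.integer(populationSize),
       generations = as.integer(generations), crossoverRate = crossoverRate,
       mutationRate = mutationRate, elitism = as.integer(elitism),
       subsetSizeRange = as.integer(subsetSizeRange),
       fitnessFolds = as.integer(fitnessFolds))
}

.stratFolds <- function(y, nfold) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nfold), length(idx))
  }
  fold
}

#' Train a GA-kNN classifier
#'
#' A genetic algorithm searches peak subsets (sizes within
#' `params$subsetSizeRange`); the fitness of a subset is the stratified
#' `fitnessFolds`-fold cross-validated accuracy of a k-nearest-neighbour
#' classifier (Euclidean distance on per-peak z-scores) restricted to it.
#' Chromosomes are index sets; crossover draws the child from the union of
#' its parents, mutation replaces slots by random peaks, and the elite is
#' carried unchanged (elite fitness is non-decreasing). The best subset's
#' model is returned together with its outer repeated random-split
#' cross-validation (the subset is fixed; only the k-NN exemplars are refit
#' per split).
#'
#' @param fm a [PeakFeatureMatrix-class] or samples x features matrix.
#' @param labels class labels.
#' @param k number of neighbours (odd).
#' @param params see [gaParams()].
#' @param seed RNG seed governing the GA and the outer CV splits.
#' @param leaveOutPct,iterations outer cross-validation settings.
#' @return list with `model` (a [ClassifierModel-class] of kind "GA"),
#'   `cv` (a [CVResult-class]) and `fitnessTrace` (elite fitness per
#'   generation).
#' @export
trainGAKNN <- function(fm, labels, k = 7L, params = gaParams(), seed = 1L,
                       leaveOutPct = 20, iterations = 10L) {
  if (k %% 2L == 0L) stop("k must be odd")
  d <- .asTraining(fm, labels)
  P <- ncol(d$X)
  rng <- params$subsetSizeRange
  if (rng[1] > P) stop("subset-size range exceeds the number of peaks")
  rng[2] <- min(rng[2], P)
  sc <- .scaleCols(d$X)
  Z <- .applyScale(d$X, sc)
  y <- d$y
  cache <- new.env(parent = emptyenv())
  trace <- numeric(0)
  best <- NULL
  withSeed(childSeed(seed, 1L), {
    fold <- .stratFolds(y, params$fitnessFolds)
    fitness <- function(sel) {
      key <- paste(sel, collapse = ",")
      if (!is.null(cache[[key]])) return(cache[[key]])
      acc <- 0
      for (f in seq_len(params$fitnessFolds)) {
        tr <- fold != f
        pred <- knnPredict(Z[tr, sel, drop = FALSE], y[tr],
                           Z[!tr, sel, drop = FALSE], k)
        acc <- acc + sum(pred == y[!tr])
      }
      val <- acc / length(y)
      cache[[key]] <- val
      val
    }
    # sample() on a length-1 vector would draw from 1:x; avoid throughout
    resample <- function(x, size) x[sample.int(length(x), size)]
    newChrom <- function()
      sort(sample.int(P, rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L))
    pop <- replicate(params$populationSize, newChrom(), simplify = FALSE)
    fit <- vapply(pop, fitness, numeric(1))
    for (g in seq_len(params$generations)) {
      o <- order(fit, lengths(pop), decreasing = c(TRUE, FALSE), method = "radix")
      elite <- pop[o[seq_len(params$elitism)]]
      trace <- c(trace, fit[o[1]])
      tournament <- function() {
        cand <- sample.int(params$populationSize, 2L)
        w <- cand[which.max(fit[cand])]
        pop[[w]]
      }
      child <- function() {
        p1 <- tournament(); p2 <- tournament()
        if (stats::runif(1) < params$crossoverRate) {
          pool <- union(p1, p2)
          size <- min(max(rng[1], resample(c(length(p1), length(p2)), 1L)),
                      length(pool))
          ch <- resample(pool, size)
        } else ch <- p1
        mut <- stats::runif(length(ch)) < params$mutationRate
        if (any(mut)) {
          repl <- setdiff(seq_len(P), ch)
          nrep <- min(sum(mut), length(repl))
          if (nrep > 0) ch[which(mut)[seq_len(nrep)]] <- resample(repl, nrep)
        }
        ch <- unique(ch)
        while (length(ch) < rng[1])
          ch <- c(ch, resample(setdiff(seq_len(P), ch), 1L))
        if (length(ch) > rng[2]) ch <- resample(ch, rng[2])
        sort(ch)
      }
      offspring <- replicate(params$populationSize - params$elitism, child(),
                             simplify = FALSE)
      pop <- c(elite, offspring)
      fit <- vapply(pop, fitness, numeric(1))
    }
    o <- order(fit, lengths(pop), decreasing = c(TRUE, FALSE), method = "radix")
    trace <- c(trace, fit[o[1]])
    best <- pop[[o[1]]]
  })
  sel <- best
  model <- .gaModel(d, sel, k)
  trainer <- function(X, yy) {
    idx <- match(sprintf("mz_%.6g", model@selectedPeaks), colnames(X))
    dd <- list(X = X[, idx, drop = FALSE], y = yy,
               centroids = model@selectedPeaks, bounds = model@decisionData$bounds)
    .gaModel(dd, seq_along(idx), k)
  }
  cv <- crossValidate(trainer, d$X, y, leaveOutPct = leaveOutPct,
                      iterations = iterations, seed = childSeed(seed, 2L))
  list(model = model, cv = cv, fitnessTrace = trace)
}

.gaModel <- function(d, sel, k) {
  sc <- .scaleCols(d$X[, sel, drop = FALSE])
  Z <- .applyScale(d$X[, sel, drop = FALSE], sc)
  new("ClassifierModel", kind = "GA", selectedPeaks = d$centroids[sel],
      decisionData = list(exemplars = unname(Z), exemplarClass = d$y,
                          k = as.integer(k),
                          bounds = .selBounds(d$bounds, d$centroids[sel])),
      scaling = sc, classLabels = .classOrder(d$y))
}

# ---- cross-validation -----------------------------------------------------

#' Repeated random-split cross-validation
#'
#' `iterations` independent stratified splits leave out `leaveOutPct` percent
#' of each class; the cross-validation percentage is the mean holdout
#' accuracy. Recognition capability is the accuracy of the final model,
#' refit on all samples, applied back to all samples (resubstitution).
#'
#' @param trainer function(X, labels) returning a [ClassifierModel-class];
#'   X is a samples x features matrix with centroid-named columns.
#' @param fm a [PeakFeatureMatrix-class] or samples x features matrix.
#' @param labels class labels.
#' @param leaveOutPct percent left out per iteration.
#' @param iterations number of random splits.
#' @param seed RNG seed for the splits.
#' @param stratified must remain TRUE; unstratified splitting can empty a
#'   class from a holdout and is refused.
#' @return a [CVResult-class].
#' @export
crossValidate <- function(trainer, fm, labels, leaveOutPct = 20,
                          iterations = 10L, seed = 1L, stratified = TRUE) {
  if (!stratified)
    stop("unstratified splitting may drop a class from a holdout; not supported")
  if (is(fm, "PeakFeatureMatrix")) {
    d <- .asTraining(fm, labels)
    X <- d$X; y <- d$y
  } else { X <- as.matrix(fm); y <- as.character(labels) }
  n <- nrow(X)
  perClass <- split(seq_len(n), y)
  if (any(vapply(perClass, length, integer(1)) < 2L))
    stop("not enough samples for a stratified holdout")
  acc <- withSeed(childSeed(seed, 7L), vapply(seq_len(iterations), function(it) {
    hold <- unlist(lapply(perClass, function(idx)
      sample(idx, max(1L, round(length(idx) * leaveOutPct / 100)))))
    m <- trainer(X[-hold, , drop = FALSE], y[-hold])
    pred <- classifySamples(m, X[hold, , drop = FALSE])
    mean(pred == y[hold]) * 100
  }, numeric(1)))
  final <- trainer(X, y)
  recog <- mean(classifySamples(final, X) == y) * 100
  new("CVResult", crossValidationPct = mean(acc), recognitionPct = recog,
      perIteration = acc,
      settings = list(leaveOutPct = leaveOutPct, iterations = iterations,
                      seed = seed))
}

# ---- classification -------------------------------------------------------

#' Classify samples with a trained model
#'
#' Accepts a samples x features matrix (columns named by centroid, as
#' produced by the trainers), a [PeakFeatureMatrix-class] (its QC flags are
#' honoured: invalid samples come back "unclassifiable"), or a single raw
#' [MassSpectrum-class] (preprocessed internally and integrated at the
#' model's stored peak bounds; a spectrum failing the quality rule is
#' "unclassifiable"). A feature input lacking one of the model's peaks is an
#' error, which is distinct from an unclassifiable sample.
#'
#' @param model a [ClassifierModel-class].
#' @param newdata matrix, [PeakFeatureMatrix-class] or [MassSpectrum-class].
#' @param ... passed to methods.
#' @return character vector of "mutant", "wild" or "unclassifiable".
#' @export
setGeneric("classifySamples", function(model, newdata, ...)
  standardGeneric("classifySamples"))

.matchModelColumns <- function(model, featureCentroids) {
  tol <- pmax(0.003 * model@selectedPeaks, 1.5)
  idx <- matchPeaks(model@selectedPeaks, featureCentroids, tol)
  if (anyNA(idx))
    stop(sprintf("feature input is missing model peak(s) at m/z %s",
                 paste(round(model@selectedPeaks[is.na(idx)], 2), collapse = ", ")))
  idx
}

.decide <- function(model, X) {
  if (is.null(colnames(X))) stop("feature columns must be centroid-named")
  idx <- .matchModelColumns(
    model, suppressWarnings(as.numeric(sub("^mz_", "", colnames(X)))))
  Xm <- X[, idx, drop = FALSE]
  Z <- .applyScale(Xm, model@scaling)
  cls <- model@classLabels
  wild <- if ("wild" %in% cls) "wild" else cls[2]
  switch(model@kind,
    QC = {
      cm <- model@decisionData$classMeans
      w <- model@decisionData$weights
      apply(Z, 1L, function(z) {
        d1 <- abs(z - cm[1, ]); d2 <- abs(z - cm[2, ])
        s1 <- sum(w[d1 < d2]); s2 <- sum(w[d2 < d1])
        if (s1 > s2) rownames(cm)[1] else if (s2 > s1) rownames(cm)[2] else wild
      })
    },
    SNN = {
      pr <- model@decisionData$prototypes
      pc <- model@decisionData$protoClass
      apply(Z, 1L, function(z) pc[which.min(rowSums(sweep(pr, 2, z)^2))])
    },
    GA = knnPredict(model@decisionData$exemplars, model@decisionData$exemplarClass,
                    Z, model@decisionData$k, tieBreak = wild))
}

#' @rdname classifySamples
#' @export
setMethod("classifySamples", signature(model = "ClassifierModel", newdata = "matrix"),
  function(model, newdata, ...) {
    unname(.decide(model, newdata))
  })

#' @rdname classifySamples
#' @param qcFlag optional per-sample flags overriding the matrix's own.
#' @export
setMethod("classifySamples",
  signature(model = "ClassifierModel", newdata = "PeakFeatureMatrix"),
  function(model, newdata, qcFlag = NULL, ...) {
    flags <- qcFlag %||% unname(qcFlags(newdata))
    out <- rep("unclassifiable", ncol(newdata))
    ok <- flags == "ok"
    if (any(ok)) {
      X <- t(peakAreas(newdata)[, ok, drop = FALSE])
      colnames(X) <- sprintf("mz_%.6g", peakDefinitions(newdata)$centroid)
      out[ok] <- .decide(model, X)
    }
    stats::setNames(out, colnames(newdata))
  })

#' @rdname classifySamples
#' @param qcMinSnr,qcMinFraction spectrum quality rule (fraction of model
#'   peaks that must reach the local SNR).
#' @export
setMethod("classifySamples",
  signature(model = "ClassifierModel", newdata = "MassSpectrum"),
  function(model, newdata, qcMinSnr = 2, qcMinFraction = 0.5, ...) {
    b <- model@decisionData$bounds
    if (is.null(b))
      stop("model carries no peak bounds; train on a PeakFeatureMatrix to classify raw spectra")
    sp <- normalizeTIC(newdata)
    sp <- smoothSpectrum(sp)
    sp <- subtractBaselineTophat(sp)
    noise <- estimateNoise(sp)
    mz <- sp@mz; y <- sp@intensity
    snr <- vapply(seq_len(nrow(b)), function(p) {
      idx <- which(mz >= b$leftBound[p] & mz <= b$rightBound[p])
      if (!length(idx)) return(0)
      max(y[idx]) / max(noise[idx[which.max(y[idx])]], .Machine$double.eps)
    }, numeric(1))
    if (mean(snr >= qcMinSnr) < qcMinFraction) return("unclassifiable")
    areas <- integrateAreas(sp, b)
    X <- matrix(areas, nrow = 1,
                dimnames = list(NULL, sprintf("mz_%.6g", b$centroid)))
    unname(.decide(model, X))
  })

# ---- persistence ----------------------------------------------------------

.modelPayload <- function(model) {
  list(kind = model@kind, selectedPeaks = model@selectedPeaks,
       decisionData = model@decisionData, scaling = model@scaling,
       classLabels = model@classLabels)
}

.payloadChecksum <- function(payload) {
  js <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}

#' Persist a classifier as structured text (JSON)
#'
#' The file carries a format version, the package version, the model payload
#' at full numeric precision and an md5 checksum of the payload; a reloaded
#' model classifies every input identically.
#'
#' @param model a [ClassifierModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ClassifierModel"))
  payload <- .modelPayload(model)
  doc <- list(format = "pepClassify-model", formatVersion = 1L,
              package = as.character(utils::packageVersion("pepClassify")),
              checksum = .payloadChecksum(payload), model = payload)
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("load error: ", conditionMessage(e)))
  if (!identical(doc$format, "pepClassify-model") || is.null(doc$model))
    stop("load error: not a pepClassify model file")
  if (!identical(as.integer(doc$formatVersion), 1L))
    stop("load error: unsupported model format version ", doc$formatVersion)
  m <- doc$model
  dd <- m$decisionData
  if (!is.null(dd$exemplars)) dd$exemplars <- as.matrix(dd$exemplars)
  if (!is.null(dd$prototypes)) dd$prototypes <- as.matrix(dd$prototypes)
  if (!is.null(dd$classMeans)) {
    cm <- as.matrix(dd$classMeans)
    rownames(cm) <- m$classLabels
    dd$classMeans <- cm
  }
  if (!is.null(dd$k)) dd$k <- as.integer(dd$k)
  if (!is.null(dd$bounds)) dd$bounds <- as.data.frame(dd$bounds)
  payload <- list(kind = m$kind, selectedPeaks = m$selectedPeaks,
                  decisionData = dd,
                  scaling = list(center = m$scaling$center,
                                 scale = m$scaling$scale),
                  classLabels = m$classLabels)
  if (!identical(unname(.payloadChecksum(payload)), unname(doc$checksum)))
    stop("load error: checksum mismatch (file corrupted or edited)")
  new("ClassifierModel", kind = payload$kind,
      selectedPeaks = payload$selectedPeaks, decisionData = payload$decisionData,
      scaling = payload$scaling, classLabels = payload$classLabels)
}
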