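# Independent oracles and cheap fixtures shared across the suite.

# Build a profile spectrum from scratch: Gaussian peaks + baseline + noise.
gaussSpectrum <- function(id = "g", centers = numeric(0), areas = numeric(0),
                          sigmas = rep(1, length(centers)),
                          mzRange = c(800, 2000), step = 0.25,
                          baseline = function(m) rep(0, length(m)),
                          noiseSd = 0, seed = 1) {
  mz <- seq(mzRange[1], mzRange[2], by = step)
  y <- baseline(mz)
  for (j in seq_along(centers))
    y <- y + areas[j] * dnorm(mz, centers[j], sigmas[j])
  if (noiseSd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(mz), 0, noiseSd)
  }
  MassSpectrum(id, mz, pmax(y, 0), metadata = list())
}

# A cheap simulation config for plumbing tests (tiny grid, two peaks).
tinyConfig <- function(nMutant = 3L, nWild = 3L, baselineAmplitude = 2,
                       noiseSigma = 0.05, ...) {
  simulationConfig(
    nMutant = nMutant, nWild = nWild, mzRange = c(800, 900), gridStep = 0.5,
    discriminatingPeaks = data.frame(centroid = 840, meanWild = 5, sdWild = 1,
                                     meanMutant = 10, sdMutant = 2),
    backgroundPeaks = data.frame(centroid = 870, mean = 8, sd = 2),
    baselineAmplitude = baselineAmplitude, noiseSigma = noiseSigma,
    resolution = 1 / 500, ...)
}

trapzOracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Welch two-sample t-test from the definition.
welchOracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# Cohen's kappa from the definition on a 2x2 table.
kappaOracle <- function(tab) {
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  (po - pe) / (1 - pe)
}

# Two-group log-rank chi-squared from a step-by-step risk table.
logrankOracle <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  g1 <- rep(c(TRUE, FALSE), c(length(t1), length(t2)))
  U <- 0; V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    atRisk <- time >= tt
    n <- sum(atRisk); n1 <- sum(atRisk & g1)
    d <- sum(event == 1 & time == tt)
    o1 <- sum(event == 1 & time == tt & g1)
    U <- U + o1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Brute-force k-NN: explicit loops, stable order on distance ties.
knnOracle <- function(trainX, trainY, testX, k) {
  out <- character(nrow(testX))
  for (i in seq_len(nrow(testX))) {
    d <- numeric(nrow(trainX))
    for (j in seq_len(nrow(trainX)))
      d[j] <- sum((testX[i, ] - trainX[j, ])^2)
    nb <- trainY[order(d)[seq_len(k)]]
    tab <- sort(table(nb), decreasing = TRUE)
    out[i] <- if (length(tab) > 1 && tab[1] == tab[2]) "wild" else names(tab)[1]
  }
  out
}

# Brute-force morphological opening (sliding min then max, shrinking windows).
openingOracle <- function(x, k) {
  n <- length(x); h <- k %/% 2
  ero <- vapply(seq_len(n), function(i) min(x[max(1, i - h):min(n, i + h)]),
                numeric(1))
  vapply(seq_len(n), function(i) max(ero[max(1, i - h):min(n, i + h)]),
         numeric(1))
}

# Fisher exact two-sided p for a 2x2 table by hypergeometric enumeration.
fisherOracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  pr <- dhyper(support, m, n, kk)
  obs <- dhyper(tab[1, 1], m, n, kk)
  sum(pr[pr <= obs * (1 + 1e-7)])
}
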