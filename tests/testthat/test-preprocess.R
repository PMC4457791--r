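test_that("TIC normalization rescales to the target and is idempotent", {
  sp <- MassSpectrum("n", 1:4, c(1, 2, 3, 4))
  out <- normalizeTIC(sp, targetTic = 1)
  # independent trapezoid summation
  expect_equal(trapzOracle(mzValues(out), intensityValues(out)), 1.0,
               tolerance = 1e-12)
  expect_equal(intensityValues(out), c(1, 2, 3, 4) / 7.5)
  again <- normalizeTIC(out, targetTic = 1)
  expect_equal(intensityValues(again), intensityValues(out), tolerance = 1e-12)
  # shape preserved up to a scalar on a random simulated spectrum
  rsp <- simulateSpectrum("wild", tinyConfig(), seed = 40)
  rout <- normalizeTIC(rsp)
  expect_equal(trapzOracle(mzValues(rout), intensityValues(rout)), 1.0,
               tolerance = 1e-9)
  ratio <- intensityValues(rsp)[intensityValues(rsp) > 0] /
    intensityValues(rout)[intensityValues(rsp) > 0]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  expect_error(normalizeTIC(MassSpectrum("z", 1:3, c(0, 0, 0))), "degenerate")
})

test_that("recalibration recovers an injected affine distortion", {
  centers <- c(1000, 1400, 1900, 2400, 3000, 3600, 4200, 4700)
  mkSpec <- function(id, scale, offset)
    gaussSpectrum(id, centers * scale + offset, areas = rep(50, 8),
                  sigmas = centers / 1500, mzRange = c(800, 5000),
                  baseline = function(m) rep(0.5, length(m)))
  # zero distortion: fitted warps are the identity
  clean <- lapply(1:6, function(i) mkSpec(paste0("c", i), 1, 0))
  rec0 <- recalibrateSpectra(clean)
  expect_true(all(abs(rec0$warps$scale - 1) < 1e-6))
  expect_true(all(abs(rec0$warps$offset) < 1e-3))
  # the same scale 1.001 / offset 0.5 Da on every spectrum, with a known
  # reference: the fitted warp composed with the distortion is the identity
  warped <- lapply(1:6, function(i) mkSpec(paste0("w", i), 1.001, 0.5))
  rec <- recalibrateSpectra(warped, reference = centers)
  expect_false(any(rec$warps$failed))
  aComp <- rec$warps$scale * 1.001
  bComp <- rec$warps$scale * 0.5 + rec$warps$offset
  expect_true(all(abs(aComp - 1) < 0.01))
  expect_true(all(abs(bComp) < 0.05))
  # corrected peak positions match the truth
  for (cc in c(1000, 3000, 4700)) {
    resid <- rec$warps$scale * (1.001 * cc + 0.5) + rec$warps$offset - cc
    expect_true(all(abs(resid) < 0.1))
  }
})

test_that("recalibration error paths flag and pass spectra through", {
  onePeak <- lapply(1:4, function(i)
    gaussSpectrum(paste0("s", i), 2000, 60, 2, mzRange = c(1900, 2100)))
  expect_warning(rec <- recalibrateSpectra(onePeak), "fewer than 2")
  expect_true(all(rec$warps$failed))
  expect_equal(intensityValues(rec$spectra[[2]]),
               intensityValues(onePeak[[2]]))
})

test_that("polynomial smoothing keeps constants, averages noise and preserves area", {
  const <- MassSpectrum("c", seq(800, 900, 0.5), rep(3, 201))
  expect_equal(intensityValues(smoothSpectrum(const, window = 5)),
               rep(3, 201), tolerance = 1e-9)
  # order 0 = moving average: white-noise variance shrinks by ~ window length
  set.seed(61)
  noise <- MassSpectrum("n", seq(0.25, 2500, 0.25), rnorm(10000, 100, 1))
  w <- 11
  sm <- smoothSpectrum(noise, window = w * 0.25, order = 0)
  mid <- 500:9500
  ratio <- var(intensityValues(noise)[mid] - 100) /
    var(intensityValues(sm)[mid] - 100)
  expect_gt(ratio, w * 0.7); expect_lt(ratio, w * 1.4)
  # a peak wider than the window keeps its area within 0.5%
  peak <- gaussSpectrum("p", 1500, 80, sigmas = 20, mzRange = c(1300, 1700))
  smp <- smoothSpectrum(peak, window = 5, order = 3)
  expect_lt(abs(trapzOracle(mzValues(smp), intensityValues(smp)) - 80) / 80,
            0.005)
  expect_error(smoothSpectrum(MassSpectrum("s", 1:4, rep(1, 4)), window = 9),
               "wider than the spectrum")
})

test_that("morphological opening matches a brute-force oracle and is idempotent", {
  set.seed(62)
  x <- abs(rnorm(400, 2, 1)) + 3 * dnorm(seq_len(400), 200, 5) * 50
  for (k in c(5, 31, 101)) {
    got <- morphologicalOpening(x, k)
    expect_equal(got, openingOracle(x, k), tolerance = 1e-12)
    expect_equal(morphologicalOpening(got, k), got, tolerance = 1e-12)
    expect_true(all(got <= x + 1e-12))
  }
})

test_that("top-hat baseline subtraction annihilates offsets and keeps narrow peaks", {
  mz <- seq(800, 10000, 2)
  const <- MassSpectrum("c", mz, rep(7, length(mz)))
  out <- subtractBaselineTophat(const)
  expect_equal(intensityValues(out), rep(0, length(mz)), tolerance = 1e-12)
  # narrow Gaussian (sigma = 0.1% of range) on a linear ramp: apex recovered
  sigma <- 0.001 * (10000 - 800)
  ramp <- function(m) 5 + (m - 800) * 1e-3
  sp <- gaussSpectrum("g", 5000, 100 * sigma * sqrt(2 * pi), sigma,
                      mzRange = c(800, 10000), step = 2, baseline = ramp)
  bs <- subtractBaselineTophat(sp, zeroLevelWindow = NULL)
  apexIdx <- which.max(intensityValues(bs))
  expect_equal(mzValues(bs)[apexIdx], 5000, tolerance = 2)
  expect_lt(abs(max(intensityValues(bs)) - 100) / 100, 0.02)
  expect_true(all(intensityValues(bs) >= -1e-12))
})

test_that("noise estimation is calibrated and robust to sparse peaks", {
  set.seed(63)
  mz <- seq(800, 3300, 0.25)
  pure <- MassSpectrum("p", mz, rnorm(length(mz), 0, 2) + 50)
  est <- estimateNoise(pure)
  expect_lt(abs(median(est) - 2) / 2, 0.10)
  y <- rnorm(length(mz), 0, 2) + 50
  at <- seq(1000, 9000, length.out = 5)
  y <- y + vapply(seq_along(mz), function(i) 0, numeric(1))
  for (cc in c(1200, 1700, 2200, 2700, 3100)) y <- y + 500 * dnorm(mz, cc, 2)
  withPeaks <- MassSpectrum("wp", mz, y)
  est2 <- estimateNoise(withPeaks)
  expect_lt(abs(median(est2) - 2) / 2, 0.15)
  zero <- MassSpectrum("z", 1:10, rep(0, 10))
  expect_equal(unique(estimateNoise(zero)), 0)
})

test_that("peak detection recovers injected peaks and rejects pure noise", {
  mz <- seq(800, 2000, 0.25)
  set.seed(64)
  noiseSd <- 0.5
  one <- MassSpectrum("one", mz,
                      pmax(rnorm(length(mz), 0, noiseSd), -3 * noiseSd) +
                        50 * noiseSd * exp(-(mz - 1400)^2 / (2 * 3^2)))
  sm <- smoothSpectrum(one, window = 2)
  pk <- detectPeaks(sm, noise = noiseSd / 2)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$centroid - 1400), 1)
  # pure noise at the threshold: nothing detected
  set.seed(65)
  pure <- MassSpectrum("none", mz, rnorm(length(mz), 0, noiseSd))
  expect_identical(nrow(detectPeaks(pure, noise = noiseSd, snrThreshold = 5)), 0L)
  # two peaks 6 sigma apart resolve with non-overlapping bounds
  sep <- gaussSpectrum("two", c(1400, 1400 + 6 * 3), c(60, 60), c(3, 3),
                       mzRange = c(800, 2000))
  pk2 <- detectPeaks(sep, noise = 0.05)
  expect_identical(nrow(pk2), 2L)
  expect_lte(pk2$rightBound[1], pk2$leftBound[2])
})

test_that("zero-level integration is exact, additive and clipped", {
  mz <- seq(800, 1200, 0.25)
  zero <- MassSpectrum("z", mz, rep(0, length(mz)))
  defs <- data.frame(centroid = 1000, leftBound = 980, rightBound = 1020)
  expect_equal(integrateAreas(zero, defs), 0)
  # isolated Gaussian fully inside its bounds
  g <- gaussSpectrum("g", 1000, 42, 3, mzRange = c(800, 1200))
  expect_lt(abs(integrateAreas(g, defs) - 42) / 42, 0.05)
  # two abutting definitions over a flat-top region sum to the single integral
  flat <- MassSpectrum("f", mz, rep(2, length(mz)))
  pair <- data.frame(centroid = c(990, 1010), leftBound = c(980, 1000),
                     rightBound = c(1000, 1020))
  whole <- data.frame(centroid = 1000, leftBound = 980, rightBound = 1020)
  expect_equal(sum(integrateAreas(flat, pair, recentroid = FALSE)),
               integrateAreas(flat, whole, recentroid = FALSE),
               tolerance = 1e-12)
  out <- data.frame(centroid = 500, leftBound = 400, rightBound = 600)
  expect_error(integrateAreas(g, out), "outside the spectrum")
})

test_that("the noise-free processing chain recovers an injected area within 5%", {
  base <- function(m) 20 * exp(-(m - 800) / 1500) + 1
  sp <- gaussSpectrum("a", 3000, 35, 3000 / 3000, mzRange = c(800, 5000),
                      baseline = base)
  proc <- subtractBaselineTophat(smoothSpectrum(sp))
  defs <- data.frame(centroid = 3000, leftBound = 2990, rightBound = 3010)
  got <- integrateAreas(proc, defs)
  expect_lt(abs(got - 35) / 35, 0.05)
})

test_that("detection power and false-positive rate meet the stated bounds", {
  mz <- seq(1000, 2000, 0.25)
  hits <- 0L; fp <- 0L
  for (r in 1:50) {
    set.seed(700 + r)
    noiseSd <- 1
    y <- rnorm(length(mz), 0, noiseSd)
    sm <- smoothSpectrum(MassSpectrum("s", mz, y), window = 2)
    nEst <- estimateNoise(sm)
    fp <- fp + nrow(detectPeaks(sm, nEst, snrThreshold = 5))
    # injected peak with apex SNR 10 on the smoothed scale
    apex <- 10 * median(nEst)
    y2 <- y + apex * exp(-(mz - 1500)^2 / (2 * 2^2))
    sm2 <- smoothSpectrum(MassSpectrum("s2", mz, y2), window = 2)
    pk <- detectPeaks(sm2, estimateNoise(sm2), snrThreshold = 5)
    hits <- hits + any(abs(pk$centroid - 1500) < 2)
  }
  expect_gte(hits, 50L * 0.99)
  expect_lt(fp / 50, 1)
})

test_that("the feature matrix recovers planted peaks and honours input order", {
  cfg <- simulationConfig(nMutant = 10L, nWild = 10L, seed = 42L)
  coh <- simulateCohort(cfg)
  fm <- buildFeatureMatrix(coh$spectra, mzRange = c(800, 10000))
  pd <- peakDefinitions(fm)
  planted <- defaultDiscriminatingPeaks()$centroid
  miss <- vapply(planted, function(cc) min(abs(pd$centroid - cc)), numeric(1))
  expect_true(all(miss < 1.5))
  expect_true(all(pd$leftBound < pd$centroid & pd$centroid < pd$rightBound))
  ov <- pd$rightBound[-nrow(pd)] <= pd$leftBound[-1] + 1e-9
  expect_true(all(ov))
  a <- peakAreas(fm)
  expect_true(all(a[, qcFlags(fm) == "ok"] >= 0))
  # invalid_rate = 0 leaves no flags
  cfg0 <- simulationConfig(nMutant = 4L, nWild = 4L, invalidRate = 0,
                           mzRange = c(3000, 5000), seed = 43L)
  coh0 <- simulateCohort(cfg0)
  fm0 <- buildFeatureMatrix(coh0$spectra)
  expect_true(all(qcFlags(fm0) == "ok"))
  # shuffling the input order permutes columns but not definitions
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  fmP <- buildFeatureMatrix(coh0$spectra[perm])
  expect_equal(peakDefinitions(fmP), peakDefinitions(fm0))
  expect_equal(unname(peakAreas(fmP)), unname(peakAreas(fm0)[, perm]))
})

test_that("low-quality spectra are flagged invalid with all-missing areas", {
  cfg <- simulationConfig(nMutant = 6L, nWild = 6L, invalidRate = 0,
                          mzRange = c(3000, 5000), seed = 44L)
  coh <- simulateCohort(cfg)
  lq <- simulateSpectrum("wild", cfg, seed = 999L, sampleIdLabel = "LQ",
                         lowQuality = TRUE)
  fm <- buildFeatureMatrix(c(coh$spectra, list(lq)))
  flags <- qcFlags(fm)
  expect_identical(unname(flags["LQ"]), "invalid")
  expect_true(all(is.na(peakAreas(fm)[, "LQ"])))
  expect_true(all(flags[names(flags) != "LQ"] == "ok"))
})
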