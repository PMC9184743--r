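test_that("epoch normalization gives mean 0, SD 1, and affine invariance", {
  expect_equal(normalizeEpoch(c(0, 2)), c(-1, 1))  # population SD
  set.seed(1)
  x <- rnorm(500, 4, 3)
  z <- normalizeEpoch(x)
  expect_equal(mean(z), 0)
  expect_equal(popSdOracle(z), 1)
  expect_equal(normalizeEpoch(z), z)
  expect_equal(normalizeEpoch(2.5 * x - 7), z)
  expect_error(normalizeEpoch(rep(1, 10)), "degenerate")
})

test_that("power spectrum has 0.4 Hz bins at study settings and satisfies Parseval", {
  set.seed(2)
  x <- rnorm(2500)
  ps <- powerSpectrum(x, 1000)
  expect_equal(ps$freqs[2] - ps$freqs[1], 0.4)
  expect_equal(length(ps$power), 1251)
  # one-sided power sums to N * var
  expect_equal(sum(ps$power), 2500 * mean((x - mean(x))^2) + 2500 * mean(x)^2,
               tolerance = 1e-6)

  # on-grid 10 Hz sinusoid: single dominant bin at exactly 10.0 Hz
  s <- sin(2 * pi * 10 * seq(0, by = 1 / 1000, length.out = 2500))
  pss <- powerSpectrum(s, 1000)
  k <- which.max(pss$power)
  expect_equal(pss$freqs[k], 10)
  expect_gt(pss$power[k] / sum(pss$power), 0.99)

  expect_error(powerSpectrum(1, 1000), "2 samples")
})

test_that("white-noise mean spectrum is flat over 1-40 Hz", {
  set.seed(3)
  avg <- rowMeans(vapply(1:300, function(i)
    powerSpectrum(rnorm(2500), 1000)$power, numeric(1251)))
  f <- (0:1250) * 0.4
  sel <- f >= 1 & f <= 40
  expect_lt(max(avg[sel]) / min(avg[sel]), 1.5)
})

test_that("relative power normalizes within the analysis range", {
  set.seed(4)
  ps <- powerSpectrum(rnorm(2500), 1000)
  rel <- relativePower(ps$power, ps$freqs)
  expect_equal(sum(rel), 1, tolerance = 1e-9)
  expect_true(all(rel >= 0))
  # 0 Hz bin excluded by the default range
  expect_equal(rel[1], 0)

  t <- seq(0, by = 1e-3, length.out = 2500)
  s <- sin(2 * pi * 10 * t)
  relS <- relativePower(powerSpectrum(s, 1000)$power, ps$freqs)
  expect_gt(bandPower(relS, ps$freqs, c(8, 14)), 0.99)

  # equal-power on-grid theta + beta mix (4.8 and 20 Hz are exact bin
  # centers at 0.4 Hz spacing): each band gets exactly half
  mix <- sin(2 * pi * 4.8 * t) + sin(2 * pi * 20 * t)
  relM <- relativePower(powerSpectrum(mix, 1000)$power, ps$freqs)
  expect_equal(bandPower(relM, ps$freqs, c(4, 7)), 0.5, tolerance = 1e-6)
  expect_equal(bandPower(relM, ps$freqs, c(15, 30)), 0.5, tolerance = 1e-6)

  expect_error(relativePower(ps$power, ps$freqs, c(600, 700)), "range")
  expect_error(bandPower(relS, ps$freqs, c(10.01, 10.02)), "empty band")
})

test_that("disjoint bands covering the range sum to 1 and respect edges", {
  set.seed(5)
  ps <- powerSpectrum(rnorm(2500), 1000)
  rel <- relativePower(ps$power, ps$freqs)
  # contiguous on the 0.4 Hz bin grid: 10.0 | 10.4 ... 25.2 | 25.6 ... 40
  cover <- list(c(0.4, 10), c(10.4, 25.2), c(25.6, 40))
  expect_equal(sum(vapply(cover, function(b) bandPower(rel, ps$freqs, b), 0)),
               1, tolerance = 1e-9)
})

test_that("relative spectra are invariant to global amplitude scaling", {
  prof <- synthProfile(spectralSlope = 1.2, backgroundSd = 5, noiseSd = 0)
  rec <- generateSubject(prof, 2, 2500, 1000, "Cz", seed = 6)
  big <- rec
  big@data <- rec@data * 37
  expect_equal(gridValues(spdGrid(big)), gridValues(spdGrid(rec)))
})

test_that("spd averaging keeps unit-sum rows and records epoch counts", {
  prof <- synthProfile(spectralSlope = 1, backgroundSd = 5)
  rec <- generateSubject(prof, 5, 2500, 1000, tinyChans, seed = 7)
  g <- spdGrid(rec)
  expect_s4_class(g, "SpdGrid")
  expect_equal(unname(rowSums(gridValues(g))), rep(1, 2), tolerance = 1e-9)
  expect_true(all(g@nEpochsAveraged == 5))
  expect_error(spdAverage(list()), "empty")
})

test_that("steeper slope raises the low-band share and shifts entropy balance", {
  # cross-module coherence: one knob (the 1/f slope) moves band power and
  # multiscale entropy together
  lowShare <- function(alpha, seed) {
    prof <- synthProfile(spectralSlope = alpha, backgroundSd = 5, noiseSd = 0.2)
    rec <- generateSubject(prof, 2, 2500, 1000, "Cz", seed)
    v <- gridValues(spdGrid(rec))[1, ]
    bandPower(v, featureValues(spdGrid(rec)), c(0.4, 7))
  }
  flat <- mean(vapply(1:6, function(i) lowShare(0.8, i), 0))
  steep <- mean(vapply(1:6, function(i) lowShare(1.8, i), 0))
  expect_gt(steep, flat)

  entAt <- function(alpha, scale, seed) {
    x <- coloredNoise(2500, alpha, 1000, seed)
    r <- 0.5 * popSdOracle(x)
    sampleEntropy(coarseGrain(x, scale), 2, r)
  }
  # the coarse-scale rise with slope holds in the near-pink regime (it
  # reverses again for very steep, random-walk-like spectra)
  fineFlat <- mean(vapply(1:12, function(i) entAt(0.6, 1, i), 0))
  fineSteep <- mean(vapply(1:12, function(i) entAt(1.2, 1, i), 0))
  coarseFlat <- mean(vapply(1:12, function(i) entAt(0.6, 40, i), 0))
  coarseSteep <- mean(vapply(1:12, function(i) entAt(1.2, 40, i), 0))
  expect_lt(fineSteep, fineFlat)      # steeper slope: less fine-scale entropy
  expect_gt(coarseSteep, coarseFlat)  # ... and more coarse-scale entropy
})
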