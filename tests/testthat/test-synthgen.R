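test_that("colored noise is zero-mean, deterministic, and slope-exact", {
  x <- coloredNoise(2500, 2, 1000, seed = 7)
  y <- coloredNoise(2500, 2, 1000, seed = 7)
  expect_identical(x, y)
  expect_lt(abs(mean(x)), 1e-12)
  expect_false(identical(x, coloredNoise(2500, 2, 1000, seed = 8)))
  expect_error(coloredNoise(1, 1, 1000, 1), "nSamples")

  # fitted log-log slope of the mean periodogram over 1-40 Hz
  fitSlope <- function(alpha, nreal) {
    ps <- rowMeans(vapply(seq_len(nreal), function(i) {
      p <- powerSpectrum(coloredNoise(2500, alpha, 1000, 1000 + i), 1000)
      p$power[-1]
    }, numeric(1250)))
    f <- (1:1250) * 0.4
    sel <- f >= 1 & f <= 40
    unname(coef(lm(log(ps[sel]) ~ log(f[sel])))[2])
  }
  expect_lt(abs(fitSlope(0, 60)), 0.1)          # white: flat
  expect_lt(abs(fitSlope(1, 200) - (-1)), 0.15) # pink: slope -1
})

test_that("band components concentrate power where placed", {
  prof <- synthProfile(spectralSlope = 1, backgroundSd = 0, noiseSd = 0,
                       bandComponents = data.frame(centerHz = 10,
                                                   bandwidthHz = 2,
                                                   relativeAmplitude = 1))
  rec <- generateSubject(prof, 4, 2500, 1000, "Cz", seed = 3)
  g <- spdGrid(rec)
  alphaShare <- bandSummary(g)[, "alpha"]
  expect_gt(alphaShare, 0.9)
})

test_that("artifact injection contaminates exactly the booked epochs", {
  prof <- synthProfile(spectralSlope = 1, backgroundSd = 3, noiseSd = 0.2,
                       artifactRate = 0.2, artifactAmplitude = 150)
  rec <- generateSubject(prof, 50, 2500, 1000, tinyChans, seed = 9)
  booked <- rec@metadata$artifactEpochs
  expect_length(booked, 10)  # 0.2 * 50 exactly
  d <- epochData(rec)
  ptp <- apply(d, 1, function(ep) max(apply(ep, 1, function(x) max(x) - min(x))))
  expect_identical(which(ptp > 100), booked)
})

test_that("generateSubject validates its arguments", {
  prof <- synthProfile()
  expect_error(generateSubject(prof, 2, 2500, 1000, character(0), 1), "empty")
  highBand <- synthProfile(bandComponents = data.frame(
    centerHz = 600, bandwidthHz = 5, relativeAmplitude = 1))
  expect_error(generateSubject(highBand, 2, 2500, 1000, "Cz", 1), "twice")
})

test_that("study generation is deterministic bookkeeping over the design", {
  spec <- nullStudySpec(nSubjects = 10, nEpochs = 2, epochMs = 1000, fs = 250,
                        channels = tinyChans, seed = 21)
  recs <- generateStudy(spec)
  expect_length(recs, 40)  # 2 groups x 2 conditions x 10 subjects
  design <- attr(recs, "design")
  wanted <- unlist(lapply(design@groups, function(g)
    lapply(design@conditions, function(cn)
      paste(g, cn, design@subjects[[g]], sep = "."))))
  expect_setequal(names(recs), wanted)
  recs2 <- generateStudy(spec)
  expect_identical(lapply(recs, epochData), lapply(recs2, epochData))
})

test_that("duplicate subject ids are rejected", {
  expect_error(studyDesign(c("a", "b"), "pre",
                           list(a = c("s1", "s2"), b = c("s2", "s3"))),
               "duplicate")
})

test_that("subject identity persists across conditions, and cells differ by profile", {
  base <- synthProfile(spectralSlope = 1, backgroundSd = 5,
                       bandComponents = data.frame(centerHz = 10, bandwidthHz = 2,
                                                   relativeAmplitude = 1))
  boosted <- base
  boosted@bandComponents$relativeAmplitude <- 3
  design <- studyDesign("g", c("pre", "post"), 6)
  spec <- synthStudySpec(design, list(g.pre = base, g.post = boosted),
                         nEpochs = 2, epochMs = 1000, fs = 250,
                         channels = "Cz", seed = 5)
  recs <- generateStudy(spec)
  share <- function(rec) mean(bandSummary(spdGrid(rec, c(1, 40)))[, "alpha"])
  pre <- vapply(design@subjects$g, function(s) share(recs[[paste("g.pre", s, sep = ".")]]), 0)
  post <- vapply(design@subjects$g, function(s) share(recs[[paste("g.post", s, sep = ".")]]), 0)
  # the boosted condition has a higher alpha share for every subject
  expect_true(all(post > pre))
})

test_that("steeper 1/f slope lowers fine-scale entropy monotonically", {
  fineEnt <- function(alpha) {
    mean(vapply(1:20, function(i) {
      x <- coloredNoise(1000, alpha, 1000, 4000 + i)
      sampleEntropy(x, 2, 0.5 * popSdOracle(x))
    }, 0))
  }
  e <- vapply(c(0, 0.8, 1.6), fineEnt, 0)
  expect_true(all(diff(e) < 0))
})
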