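# Synthetic multichannel EEG with controllable spectral and entropy
# structure, plus full study layouts (group x condition x subject), so every
# downstream stage is testable and calibratable without recordings.

# Deterministic seed derivation (study seed -> subject seed -> epoch seed).
# Linear congruential mixing mod 2^31 - 1; result always a positive integer
# below 2^31 so set.seed() is safe on 32-bit R integers.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 2246822519 + 1013904223) %% 2147483647)
}

#' Generate 1/f^alpha colored noise
#'
#' Spectral-shaping generator: white Gaussian noise is shaped in the
#' frequency domain by an amplitude profile proportional to f^(-alpha/2)
#' and inverse-transformed, giving exact slope control in O(n log n).
#' The DC bin is zeroed (zero-mean output) and the series is normalized to
#' unit population SD; callers scale to the microvolt level they need.
#'
#' @param nSamples series length (>= 2).
#' @param alpha spectral exponent (>= 0); 0 gives white noise.
#' @param fs sampling rate in Hz (sets the frequency axis).
#' @param seed integer seed; the output is fully determined by it.
#' @return Numeric vector of length `nSamples`, zero-mean, unit SD.
#' @export
coloredNoise <- function(nSamples, alpha, fs, seed) {
  if (nSamples < 2) stop("nSamples must be >= 2")
  if (alpha < 0) stop("alpha must be >= 0")
  set.seed(seed)
  .shapedNoise(nSamples, fs, function(f) f^(-alpha / 2))
}

# Hermitian-symmetric frequency-domain shaping of white Gaussian noise.
# ampFun maps frequency (Hz, > 0) to an amplitude multiplier.
.shapedNoise <- function(n, fs, ampFun) {
  nPos <- floor(n / 2)                 # bins 1..nPos (nPos = Nyquist if n even)
  f <- (1:nPos) * fs / n
  a <- ampFun(f)
  z <- complex(real = rnorm(nPos), imaginary = rnorm(nPos)) / sqrt(2)
  if (n %% 2 == 0) z[nPos] <- complex(real = Re(z[nPos]) * sqrt(2), imaginary = 0)
  spec <- complex(length.out = n)
  spec[2:(nPos + 1)] <- a * z
  if (n %% 2 == 0) {
    if (nPos > 1) spec[n:(n - nPos + 2)] <- Conj(spec[2:nPos])
  } else {
    spec[n:(n - nPos + 1)] <- Conj(spec[2:(nPos + 1)])
  }
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s > 0) x / s else x
}

# Band-limited Gaussian noise: Gaussian spectral envelope centered at
# centerHz with FWHM bandwidthHz, unit SD.
.bandNoise <- function(n, fs, centerHz, bandwidthHz) {
  sig <- bandwidthHz / (2 * sqrt(2 * log(2)))
  .shapedNoise(n, fs, function(f) exp(-((f - centerHz)^2) / (2 * sig^2)))
}

#' Generate one synthetic epoched recording
#'
#' Each epoch is an independent realization of: a 1/f^alpha background
#' (SD `backgroundSd` uV), plus band-limited Gaussian oscillations at the
#' profile's relative amplitudes (relative to the background SD, or in uV
#' when the background is disabled), plus white measurement noise.
#' `round(artifactRate * nEpochs)` epochs additionally receive a one-cycle
#' sinusoidal transient of peak-to-peak amplitude `artifactAmplitude` on one
#' channel; the affected epoch indices are recorded in
#' `metadata$artifactEpochs` so rejection exactness can be audited.
#'
#' @param profile a [SynthProfile-class].
#' @param nEpochs number of epochs.
#' @param epochMs epoch duration in ms; `epochMs * fs / 1000` must be integer.
#' @param fs sampling rate in Hz; must exceed twice the highest band center.
#' @param channels character vector of channel labels (non-empty).
#' @param seed integer seed; output is fully determined by it.
#' @return An [EpochedRecording-class].
#' @export
generateSubject <- function(profile, nEpochs, epochMs, fs, channels, seed) {
  validObject(profile)
  if (!length(channels)) stop("channel list must not be empty")
  bands <- profile@bandComponents
  if (nrow(bands) && fs <= 2 * max(bands$centerHz))
    stop("fs must exceed twice the highest band center")
  n <- epochMs * fs / 1000
  if (abs(n - round(n)) > 1e-9) stop("epochMs * fs / 1000 must be an integer")
  n <- as.integer(round(n))
  nc <- length(channels)
  oscScale <- if (profile@backgroundSd > 0) profile@backgroundSd else 1

  dat <- array(0, dim = c(nEpochs, nc, n))
  for (e in seq_len(nEpochs)) {
    eSeed <- deriveSeed(seed, e)
    set.seed(eSeed)
    for (ch in seq_len(nc)) {
      x <- numeric(n)
      if (profile@backgroundSd > 0)
        x <- profile@backgroundSd * .shapedNoise(n, fs, function(f) f^(-profile@spectralSlope / 2))
      if (nrow(bands)) {
        for (b in seq_len(nrow(bands))) {
          if (bands$relativeAmplitude[b] > 0)
            x <- x + oscScale * bands$relativeAmplitude[b] *
              .bandNoise(n, fs, bands$centerHz[b], bands$bandwidthHz[b])
        }
      }
      if (profile@noiseSd > 0) x <- x + rnorm(n, sd = profile@noiseSd)
      dat[e, ch, ] <- x
    }
  }

  # artifact injection: exact count, one-cycle sine (peak-to-peak =
  # artifactAmplitude) of ~100 ms on one channel per contaminated epoch
  nArt <- as.integer(round(profile@artifactRate * nEpochs))
  artEpochs <- integer(0)
  if (nArt > 0) {
    set.seed(deriveSeed(seed, 0L))
    artEpochs <- sort(sample.int(nEpochs, nArt))
    pulseLen <- max(4L, min(n, as.integer(round(0.1 * fs))))
    pulse <- (profile@artifactAmplitude / 2) * sin(2 * pi * seq_len(pulseLen) / pulseLen)
    for (e in artEpochs) {
      ch <- sample.int(nc, 1)
      start <- sample.int(n - pulseLen + 1L, 1)
      idx <- start:(start + pulseLen - 1L)
      dat[e, ch, idx] <- dat[e, ch, idx] + pulse
    }
  }

  new("EpochedRecording", data = dat, fs = fs, epochMs = epochMs,
      channelLabels = as.character(channels),
      provenance = sprintf("synthetic: slope=%.2f, %d band(s), %d/%d artifact epochs, seed=%d",
                           profile@spectralSlope, nrow(bands), nArt, nEpochs, seed),
      metadata = list(artifactEpochs = artEpochs, seed = seed))
}

#' Generate a full synthetic study
#'
#' Produces one [EpochedRecording-class] per (group, condition, subject)
#' cell of the spec's design. Subject identity is preserved across
#' conditions: each subject's band-amplitude scaling factors (Gaussian,
#' mean 1, SD `subjectSdFrac`) are drawn once from the subject's seed and
#' applied to the profile of every condition, mimicking the
#' repeated-measures pre/post structure. Per-recording seeds are derived
#' deterministically from `spec@seed`, so the whole study is reproducible
#' and any single recording can be regenerated in isolation.
#'
#' @param spec a [SynthStudySpec-class].
#' @return Named list of recordings keyed `"group.condition.subject"`, with
#'   the design attached as `attr(, "design")`.
#' @export
generateStudy <- function(spec) {
  validObject(spec)
  design <- spec@design
  out <- list()
  subjCounter <- 0L
  for (g in design@groups) {
    for (s in design@subjects[[g]]) {
      subjCounter <- subjCounter + 1L
      subjSeed <- deriveSeed(spec@seed, subjCounter)
      # subject-level random offset: one scaling factor per band slot,
      # shared across conditions
      maxBands <- max(vapply(design@conditions, function(cn)
        nrow(spec@profiles[[paste(g, cn, sep = ".")]]@bandComponents), 0L))
      set.seed(subjSeed)
      bandScale <- if (maxBands > 0) rnorm(maxBands, 1, spec@subjectSdFrac) else numeric(0)
      bandScale <- pmax(bandScale, 0)
      for (ci in seq_along(design@conditions)) {
        cn <- design@conditions[ci]
        prof <- spec@profiles[[paste(g, cn, sep = ".")]]
        if (nrow(prof@bandComponents)) {
          nb <- nrow(prof@bandComponents)
          prof@bandComponents$relativeAmplitude <-
            prof@bandComponents$relativeAmplitude * bandScale[seq_len(nb)]
        }
        recSeed <- deriveSeed(subjSeed, ci)
        key <- paste(g, cn, s, sep = ".")
        out[[key]] <- generateSubject(prof, spec@nEpochs, spec@epochMs,
                                      spec@fs, spec@channels, recSeed)
      }
    }
  }
  attr(out, "design") <- design
  out
}

#' Default generative profiles for the aging and training conditions
#'
#' `youngProfile()`: steep 1/f background (alpha = 1.6) with prominent
#' delta/theta activity — yields lower fine-scale and higher coarse-scale
#' entropy and a larger 1-7 Hz power share. `oldProfile()`: flatter
#' background (alpha = 1.0) with relatively more beta — higher fine-scale
#' and lower coarse-scale entropy, larger 15-30 Hz share.
#' `trainedProfile(base)` models the post-training state of a trained
#' group: the background steepens and the 3-14 Hz oscillatory components
#' strengthen, raising coarse-scale entropy and low-frequency power.
#'
#' @param artifactRate,artifactAmplitude optional artifact contamination.
#' @return A [SynthProfile-class].
#' @export
youngProfile <- function(artifactRate = 0, artifactAmplitude = 150) {
  synthProfile(
    spectralSlope = 1.6,
    bandComponents = data.frame(
      centerHz = c(5, 10, 20),
      bandwidthHz = c(4, 3, 10),
      relativeAmplitude = c(0.9, 0.8, 0.2)),
    backgroundSd = 5, noiseSd = 0.5,
    artifactRate = artifactRate, artifactAmplitude = artifactAmplitude)
}

#' @rdname youngProfile
#' @export
oldProfile <- function(artifactRate = 0, artifactAmplitude = 150) {
  synthProfile(
    spectralSlope = 1.0,
    bandComponents = data.frame(
      centerHz = c(5, 10, 20),
      bandwidthHz = c(4, 3, 10),
      relativeAmplitude = c(0.45, 0.8, 0.6)),
    backgroundSd = 5, noiseSd = 0.5,
    artifactRate = artifactRate, artifactAmplitude = artifactAmplitude)
}

#' @rdname youngProfile
#' @param base profile to modify (the trained group's pre-training state).
#' @param slopeShift added to the spectral slope post-training.
#' @param lowBandGain multiplier on the amplitude of components centered in
#'   3-14 Hz post-training.
#' @export
trainedProfile <- function(base = oldProfile(), slopeShift = 0.35, lowBandGain = 1.5) {
  prof <- base
  prof@spectralSlope <- base@spectralSlope + slopeShift
  b <- prof@bandComponents
  if (nrow(b)) {
    sel <- b$centerHz >= 3 & b$centerHz <= 14
    b$relativeAmplitude[sel] <- b$relativeAmplitude[sel] * lowBandGain
    prof@bandComponents <- b
  }
  prof
}

#' Ready-made study specifications
#'
#' `agingStudySpec()` lays out the pre-training age contrast: two groups
#' (young, old) in one condition, with the default young/old profiles.
#' `trainingStudySpec()` lays out the pre/post training design: a control
#' group whose profile does not change and a training group whose
#' post-training profile is `trainedProfile(base)`.
#' `nullStudySpec()` uses one identical profile in every cell (for null
#' calibration of the PLS permutation test).
#'
#' @param nSubjects subjects per group.
#' @param nEpochs epochs per recording (study default 48, i.e. 2 min of
#'   2500 ms epochs).
#' @param epochMs,fs epoch duration (ms) and sampling rate (Hz).
#' @param channels channel labels.
#' @param seed study seed.
#' @return A [SynthStudySpec-class].
#' @export
agingStudySpec <- function(nSubjects = 20, nEpochs = 48L, epochMs = 2500,
                           fs = 1000, channels = taskChannels(), seed = 1L) {
  design <- studyDesign(c("young", "old"), "pre", nSubjects)
  profiles <- list("young.pre" = youngProfile(), "old.pre" = oldProfile())
  synthStudySpec(design, profiles, nEpochs = nEpochs, epochMs = epochMs,
                 fs = fs, channels = channels, seed = seed)
}

#' @rdname agingStudySpec
#' @param base pre-training profile of both groups.
#' @export
trainingStudySpec <- function(nSubjects = 20, base = oldProfile(),
                              nEpochs = 48L, epochMs = 2500, fs = 1000,
                              channels = taskChannels(), seed = 1L) {
  design <- studyDesign(c("control", "training"), c("pre", "post"), nSubjects)
  profiles <- list(
    "control.pre" = base, "control.post" = base,
    "training.pre" = base, "training.post" = trainedProfile(base))
  synthStudySpec(design, profiles, nEpochs = nEpochs, epochMs = epochMs,
                 fs = fs, channels = channels, seed = seed)
}

#' @rdname agingStudySpec
#' @param profile the single profile used in every cell.
#' @param groups,conditions design layout for the null study.
#' @export
nullStudySpec <- function(nSubjects = 10, profile = oldProfile(),
                          groups = c("g1", "g2"), conditions = c("c1", "c2"),
                          nEpochs = 48L, epochMs = 2500, fs = 1000,
                          channels = taskChannels(), seed = 1L) {
  design <- studyDesign(groups, conditions, nSubjects)
  cells <- as.vector(outer(groups, conditions, paste, sep = "."))
  profiles <- setNames(rep(list(profile), length(cells)), cells)
  synthStudySpec(design, profiles, nEpochs = nEpochs, epochMs = epochMs,
                 fs = fs, channels = channels, seed = seed)
}
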