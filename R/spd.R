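# Spectral power density: normalized single-trial FFT power, relative power
# per bin and per canonical band, averaged across epochs.

#' Canonical frequency bands
#'
#' Named closed intervals in Hz: delta 1-3, theta 4-7, the low-band
#' composite 1-7, alpha 8-14, beta 15-30, gamma 30-40. The gaps between
#' band edges (7 to 8 Hz, 14 to 15 Hz) are intentional and preserved; gamma
#' is capped at the 40 Hz filter edge. All edges are configurable.
#'
#' @return Named list of `c(low, high)` vectors.
#' @export
defaultBands <- function() {
  list(delta = c(1, 3), theta = c(4, 7), low = c(1, 7),
       alpha = c(8, 14), beta = c(15, 30), gamma = c(30, 40))
}

#' Z-normalize an epoch
#'
#' Mean 0, population SD 1; removes age-related global power differences so
#' that only the relative spectral composition is compared.
#'
#' @param x numeric series with nonzero SD.
#' @return Normalized series.
#' @export
normalizeEpoch <- function(x) {
  s <- popSd(x)
  if (s == 0) stop("degenerate input: constant series cannot be normalized")
  (x - mean(x)) / s
}

#' One-sided FFT power spectrum of a single trial
#'
#' Squared magnitude of the FFT at frequencies `k * fs / N`,
#' `k = 0..floor(N/2)`; no taper, no padding, no detrending beyond the mean
#' removal in [normalizeEpoch()]. For 2500 samples at 1000 Hz the bin
#' spacing is 0.4 Hz. One-sided power is scaled so it sums to
#' `N * var(x)` (Parseval).
#'
#' @param x numeric series (one epoch, one channel), length >= 2.
#' @param fs sampling rate in Hz.
#' @return List with `power` (length `floor(N/2)+1`) and `freqs` (Hz).
#' @export
powerSpectrum <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  X <- fft(x)
  half <- floor(n / 2)
  p <- Mod(X[1:(half + 1)])^2 / n
  # fold negative frequencies onto positive ones (one-sided spectrum)
  if (n %% 2 == 0) {
    if (half > 1) p[2:half] <- 2 * p[2:half]
  } else {
    p[2:(half + 1)] <- 2 * p[2:(half + 1)]
  }
  list(power = p, freqs = (0:half) * fs / n)
}

#' Relative power within an analysis range
#'
#' Divides each bin's power by the total power over `rangeHz` (closed on
#' bin centers); bins outside the range get zero. The default range spans
#' the first nonzero bin to the 40 Hz filter edge, excluding the 0 Hz bin
#' (zeroed by mean removal anyway).
#'
#' @param power,freqs as returned by [powerSpectrum()].
#' @param rangeHz `c(low, high)` analysis range in Hz.
#' @return Vector of fractions over all bins; sums to 1 within the range.
#' @export
relativePower <- function(power, freqs, rangeHz = c(0.4, 40)) {
  sel <- freqs >= rangeHz[1] & freqs <= rangeHz[2]
  if (!any(sel)) stop("no frequency bins within the analysis range")
  tot <- sum(power[sel])
  if (tot <= 0) stop("degenerate input: zero total power in the analysis range")
  out <- numeric(length(power))
  out[sel] <- power[sel] / tot
  out
}

#' Band share of a relative spectrum
#'
#' Sum of relative power over bins whose center lies in the closed interval
#' `band = c(low, high)`.
#'
#' @param relSpectrum relative power per bin (from [relativePower()]).
#' @param freqs bin centers in Hz.
#' @param band `c(low, high)` in Hz.
#' @return Scalar fraction.
#' @export
bandPower <- function(relSpectrum, freqs, band) {
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("empty band after binning: no bin centers in [",
                      band[1], ", ", band[2], "] Hz")
  sum(relSpectrum[sel])
}

#' Average per-epoch relative spectra into an SpdGrid
#'
#' Element-wise mean of single-trial relative spectra (a mean of unit-sum
#' vectors is unit-sum over the analysis range).
#'
#' @param perEpochSpectra list of channels x bins matrices (identical grids).
#' @param freqs bin centers in Hz.
#' @param channelLabels channel labels.
#' @return An [SpdGrid-class].
#' @export
spdAverage <- function(perEpochSpectra, freqs, channelLabels = NULL) {
  if (!length(perEpochSpectra)) stop("empty epoch-spectrum list")
  dims <- dim(perEpochSpectra[[1]])
  if (!all(vapply(perEpochSpectra, function(g) all(dim(g) == dims), TRUE)))
    stop("all epoch spectra must share one bin grid")
  if (is.null(channelLabels)) {
    channelLabels <- rownames(perEpochSpectra[[1]])
    if (is.null(channelLabels)) channelLabels <- sprintf("ch%d", seq_len(dims[1]))
  }
  arr <- simplify2array(perEpochSpectra)
  dim(arr) <- c(dims[1], dims[2], length(perEpochSpectra))
  vals <- apply(arr, c(1, 2), mean)
  new("SpdGrid", values = vals, channelLabels = channelLabels,
      featureValues = as.numeric(freqs),
      nEpochsAveraged = matrix(length(perEpochSpectra), dims[1], dims[2]))
}

#' Spectral power density of an epoched recording
#'
#' Per epoch and channel: z-normalize, FFT power, relative power over
#' `rangeHz`; then average across epochs. Only bins within `rangeHz` are
#' retained in the output grid.
#'
#' @param rec an [EpochedRecording-class].
#' @param rangeHz analysis range (default 0.4-40 Hz).
#' @return An [SpdGrid-class] whose feature axis is the bin centers in Hz.
#' @export
spdGrid <- function(rec, rangeHz = c(0.4, 40)) {
  d <- epochData(rec)
  n <- dim(d)[3]
  fs <- samplingRate(rec)
  freqs <- (0:floor(n / 2)) * fs / n
  sel <- freqs >= rangeHz[1] & freqs <= rangeHz[2]
  spectra <- lapply(seq_len(dim(d)[1]), function(e) {
    m <- matrix(0, dim(d)[2], sum(sel))
    for (ch in seq_len(dim(d)[2])) {
      x <- normalizeEpoch(d[e, ch, ])
      ps <- powerSpectrum(x, fs)
      m[ch, ] <- relativePower(ps$power, ps$freqs, rangeHz)[sel]
    }
    m
  })
  spdAverage(spectra, freqs[sel], channelLabels(rec))
}

#' Band summary of an SpdGrid
#'
#' @param grid an [SpdGrid-class].
#' @param bands named list of `c(low, high)` intervals (default
#'   [defaultBands()]).
#' @return channels x bands matrix of band shares.
#' @export
bandSummary <- function(grid, bands = defaultBands()) {
  freqs <- featureValues(grid)
  v <- gridValues(grid)
  out <- vapply(bands, function(b)
    apply(v, 1, function(row) bandPower(row, freqs, b)),
    numeric(nrow(v)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(bands)))
  rownames(out) <- channelLabels(grid)
  out
}
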