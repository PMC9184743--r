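# Multiscale entropy: coarse-graining plus sample entropy per epoch,
# channel and timescale, averaged across epochs.

#' Coarse-grain a time series
#'
#' Replaces the series by means of non-overlapping windows of length
#' `scale`; the trailing remainder is discarded. Scale 1 is the identity
#' (the original series).
#'
#' @param x numeric series.
#' @param scale coarse-graining factor (integer >= 1, <= length(x)).
#' @return Numeric vector of length `floor(length(x) / scale)`.
#' @export
coarseGrain <- function(x, scale) {
  scale <- as.integer(scale)
  if (scale < 1) stop("scale must be >= 1")
  n <- length(x)
  if (scale > n) stop("scale exceeds series length")
  if (scale == 1L) return(x)
  m <- n %/% scale
  colMeans(matrix(x[seq_len(m * scale)], nrow = scale))
}

#' Sample entropy
#'
#' Returns `-ln(A/B)` where B counts pairs of length-`m` templates whose
#' Chebyshev (maximum coordinate-wise) distance is at most `rAbs`, and A
#' counts the same pairs still matching when extended by one point.
#' Self-matches are excluded (pairs over i < j); templates are the first
#' `N - m` windows for both lengths, following the reference sample-entropy
#' convention. When A or B is zero the estimate is undefined and `NaN` is
#' returned with a warning; epoch averaging excludes such cells.
#'
#' @param x numeric series of length > m + 1.
#' @param m pattern length (default 2).
#' @param rAbs absolute tolerance in the units of `x`.
#' @return Sample entropy in nats, or `NaN` if undefined.
#' @export
sampleEntropy <- function(x, m = 2L, rAbs) {
  if (length(x) <= m + 1L) stop("series too short: need length > m + 1")
  if (rAbs <= 0) stop("rAbs must be > 0")
  counts <- .sampen_counts(as.numeric(x), as.integer(m), rAbs)
  if (counts[1] == 0 || counts[2] == 0) {
    warning("sample entropy undefined (zero template match count); returning NaN")
    return(NaN)
  }
  -log(counts[2] / counts[1])
}

# population SD (1/N normalizer), the convention of the reference
# multiscale-entropy implementation
popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Multiscale entropy of one epoch
#'
#' For each channel: coarse-grain at scales `1..S` and compute sample
#' entropy with tolerance `rFrac` x the population SD of the channel's
#' original (scale-1) series — the tolerance is fixed at scale 1 and reused
#' across scales, following the reference implementation. S is capped both
#' by `maxScale` and by the rule that at least `minCoarseSamples` coarse
#' samples must remain: `S = min(maxScale, floor(N / minCoarseSamples))`.
#' With 2500-sample epochs and the defaults this yields scales 1-50.
#'
#' @param epoch channels x samples matrix (a single epoch), or a vector
#'   treated as one channel.
#' @param params an [MseParams-class].
#' @param fs sampling rate in Hz (at 1000 Hz, scale s corresponds to s-ms
#'   windows).
#' @return channels x scales matrix of sample entropy (nats); columns named
#'   by scale.
#' @export
mseCurve <- function(epoch, params = mseParams(), fs = 1000) {
  validObject(params)
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  S <- min(params@maxScale, n %/% params@minCoarseSamples)
  if (S < 1) stop("epoch too short: no scale satisfies the minimum-samples rule")
  out <- matrix(NaN, nrow = nrow(epoch), ncol = S,
                dimnames = list(rownames(epoch), seq_len(S)))
  for (ch in seq_len(nrow(epoch))) {
    x <- epoch[ch, ]
    rAbs <- params@rFrac * popSd(x)
    if (rAbs <= 0) {
      warning("constant channel: sample entropy undefined at all scales")
      next
    }
    for (s in seq_len(S)) {
      out[ch, s] <- suppressWarnings(
        tryCatch(sampleEntropy(coarseGrain(x, s), params@m, rAbs),
                 error = function(e) NaN))
    }
  }
  out
}

#' Average per-epoch entropy grids into an MseGrid
#'
#' Element-wise mean over epochs, excluding undefined (NaN) entries; the
#' per-cell count of contributing epochs is recorded. A warning reports how
#' many cells had undefined estimates dropped.
#'
#' @param perEpochGrids list of channels x scales matrices of equal shape.
#' @param channelLabels channel labels (defaults to the first grid's
#'   rownames).
#' @param params the [MseParams-class] used to compute the grids.
#' @return An [MseGrid-class].
#' @export
mseAverage <- function(perEpochGrids, channelLabels = NULL, params = mseParams()) {
  if (!length(perEpochGrids)) stop("empty epoch-grid list")
  dims <- dim(perEpochGrids[[1]])
  if (!all(vapply(perEpochGrids, function(g) all(dim(g) == dims), TRUE)))
    stop("all epoch grids must have identical shape")
  if (is.null(channelLabels)) {
    channelLabels <- rownames(perEpochGrids[[1]])
    if (is.null(channelLabels)) channelLabels <- sprintf("ch%d", seq_len(dims[1]))
  }
  arr <- simplify2array(perEpochGrids)          # channels x scales x epochs
  dim(arr) <- c(dims[1], dims[2], length(perEpochGrids))
  ok <- !is.nan(arr) & is.finite(arr)
  nOk <- apply(ok, c(1, 2), sum)
  sums <- apply(ifelse(ok, arr, 0), c(1, 2), sum)
  vals <- ifelse(nOk > 0, sums / pmax(nOk, 1), NaN)
  nDropped <- sum(!ok)
  if (nDropped > 0)
    warning(sprintf("%d undefined entropy cell(s) excluded from averaging", nDropped))
  new("MseGrid", values = vals, channelLabels = channelLabels,
      featureValues = as.numeric(seq_len(dims[2])),
      nEpochsAveraged = nOk, params = params)
}

#' Multiscale entropy of an epoched recording
#'
#' Convenience wrapper: [mseCurve()] per epoch, then [mseAverage()].
#'
#' @param rec an [EpochedRecording-class].
#' @param params an [MseParams-class].
#' @return An [MseGrid-class].
#' @export
mseGrid <- function(rec, params = mseParams()) {
  d <- epochData(rec)
  grids <- lapply(seq_len(dim(d)[1]), function(e) {
    ep <- array(d[e, , , drop = FALSE], dim = dim(d)[2:3])
    mseCurve(ep, params, samplingRate(rec))
  })
  mseAverage(grids, channelLabels = channelLabels(rec), params = params)
}
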