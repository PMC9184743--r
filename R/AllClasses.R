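#' EpochedRecording: epoched multichannel EEG
#'
#' The common currency of all signal stages: a 3-d numeric array of
#' epochs x channels x samples in microvolts, with the sampling rate,
#' channel labels, epoch duration and a free-text provenance log.
#'
#' @slot data numeric array, epochs x channels x samples (uV).
#' @slot fs sampling rate in Hz.
#' @slot epochMs epoch duration in milliseconds; `epochMs * fs / 1000`
#'   must equal the sample dimension exactly.
#' @slot channelLabels unique channel labels, one per channel row.
#' @slot provenance character log of applied processing steps.
#' @slot metadata list of generator/processing bookkeeping (e.g. indices
#'   of epochs that received an injected artifact).
#' @export
setClass("EpochedRecording",
  representation(
    data = "array",
    fs = "numeric",
    epochMs = "numeric",
    channelLabels = "character",
    provenance = "character",
    metadata = "list"
  )
)

setValidity("EpochedRecording", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3-d array (epochs x channels x samples)")
  if (anyNA(d)) return("data must not contain missing values")
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be a positive scalar")
  ns <- object@epochMs * object@fs / 1000
  if (abs(ns - round(ns)) > 1e-9) return("epochMs * fs / 1000 must be an integer")
  if (dim(d)[3] != round(ns)) return(sprintf("sample dimension (%d) != epochMs * fs / 1000 (%d)", dim(d)[3], round(ns)))
  if (dim(d)[2] != length(object@channelLabels)) return("channel dimension does not match channelLabels")
  if (anyDuplicated(object@channelLabels)) return("channelLabels must be unique")
  TRUE
})

#' RejectionReport: outcome of amplitude-based epoch rejection
#'
#' @slot nInput number of epochs examined.
#' @slot nRejected number of epochs rejected.
#' @slot rejectedIndices indices (into the input) of rejected epochs.
#' @slot thresholdUv peak-to-peak threshold in microvolts.
#' @export
setClass("RejectionReport",
  representation(
    nInput = "integer",
    nRejected = "integer",
    rejectedIndices = "integer",
    thresholdUv = "numeric"
  )
)

setValidity("RejectionReport", function(object) {
  if (object@nRejected != length(object@rejectedIndices)) return("nRejected != length(rejectedIndices)")
  if (object@nRejected > object@nInput) return("nRejected > nInput")
  TRUE
})

#' MseParams: multiscale entropy parameters
#'
#' @slot m pattern length in samples (default 2).
#' @slot rFrac tolerance as a fraction of the scale-1 series SD (default 0.5).
#' @slot maxScale largest coarse-graining factor to attempt (default 50).
#' @slot minCoarseSamples minimum coarse-grained series length for a scale
#'   to be included (default 50).
#' @export
setClass("MseParams",
  representation(
    m = "integer",
    rFrac = "numeric",
    maxScale = "integer",
    minCoarseSamples = "integer"
  )
)

setValidity("MseParams", function(object) {
  if (object@m < 1L) return("m must be >= 1")
  if (object@rFrac <= 0) return("rFrac must be > 0")
  if (object@maxScale < 1L) return("maxScale must be >= 1")
  if (object@minCoarseSamples < object@m + 2L) return("minCoarseSamples must be >= m + 2")
  TRUE
})

#' @rdname MseParams-class
#' @param m,rFrac,maxScale,minCoarseSamples see slot documentation.
#' @return An `MseParams` object.
#' @export
mseParams <- function(m = 2L, rFrac = 0.5, maxScale = 50L, minCoarseSamples = 50L) {
  new("MseParams", m = as.integer(m), rFrac = rFrac,
      maxScale = as.integer(maxScale), minCoarseSamples = as.integer(minCoarseSamples))
}

#' FeatureGrid: per-subject channel x feature matrix
#'
#' Virtual parent of [MseGrid-class], [SpdGrid-class] and [ErpGrid-class]:
#' a channels x features matrix averaged over epochs, with the feature-axis
#' values retained for un-flattening PLS salience maps.
#'
#' @slot values channels x features numeric matrix.
#' @slot channelLabels channel labels (rows).
#' @slot featureValues numeric feature-axis values (timescales in samples,
#'   frequency-bin centers in Hz, or timepoints in ms).
#' @slot nEpochsAveraged per-cell count of epochs contributing to the mean
#'   (entries where the estimate was undefined are excluded).
#' @export
setClass("FeatureGrid",
  representation(
    "VIRTUAL",
    values = "matrix",
    channelLabels = "character",
    featureValues = "numeric",
    nEpochsAveraged = "matrix"
  )
)

setValidity("FeatureGrid", function(object) {
  v <- object@values
  if (nrow(v) != length(object@channelLabels)) return("rows of values must match channelLabels")
  if (ncol(v) != length(object@featureValues)) return("columns of values must match featureValues")
  if (!all(dim(object@nEpochsAveraged) == dim(v))) return("nEpochsAveraged must match values in shape")
  TRUE
})

#' MseGrid: channels x timescales sample-entropy grid
#'
#' @slot params the [MseParams-class] used.
#' @export
setClass("MseGrid", contains = "FeatureGrid",
  representation(params = "MseParams"))

setValidity("MseGrid", function(object) {
  s <- object@featureValues
  if (length(s) && (s[1] != 1 || any(diff(s) <= 0))) return("scales must increase strictly from 1")
  TRUE
})

#' SpdGrid: channels x frequency-bins relative-power grid
#'
#' Values are unitless fractions of total power over the analysis range;
#' each channel row sums to 1.
#' @export
setClass("SpdGrid", contains = "FeatureGrid")

setValidity("SpdGrid", function(object) {
  if (any(object@values < -1e-12)) return("relative power must be non-negative")
  TRUE
})

#' ErpGrid: channels x timepoints average-amplitude grid
#'
#' Holds externally computed per-subject event-related-potential averages
#' (channels x timepoints, uV) so electrode-selection analyses run through
#' the same PLS engine as the entropy and power grids.
#' @export
setClass("ErpGrid", contains = "FeatureGrid")

#' StudyDesign: groups, conditions and subjects of a repeated-measures study
#'
#' Defines the row order of the PLS data matrix: subjects nested within
#' conditions nested within groups. Every subject appears in every
#' condition of its group.
#'
#' @slot groups ordered group names.
#' @slot conditions ordered condition names.
#' @slot subjects named list (one element per group) of ordered subject ids.
#' @export
setClass("StudyDesign",
  representation(
    groups = "character",
    conditions = "character",
    subjects = "list"
  )
)

setValidity("StudyDesign", function(object) {
  if (!length(object@groups)) return("at least one group required")
  if (!length(object@conditions)) return("at least one condition required")
  if (!identical(sort(names(object@subjects)), sort(object@groups)))
    return("subjects must be a named list with one element per group")
  ids <- unlist(object@subjects, use.names = FALSE)
  if (anyDuplicated(ids)) return("duplicate subject ids across groups")
  if (any(vapply(object@subjects, anyDuplicated, 0L) > 0)) return("duplicate subject ids within a group")
  TRUE
})

#' @rdname StudyDesign-class
#' @param groups,conditions,subjects see slot documentation. `subjects` may
#'   also be a single count, expanded to per-group ids `"<group>_s<k>"`.
#' @return A `StudyDesign` object.
#' @export
studyDesign <- function(groups, conditions, subjects) {
  if (is.numeric(subjects) && length(subjects) == 1L) {
    subjects <- setNames(
      lapply(groups, function(g) sprintf("%s_s%02d", g, seq_len(subjects))),
      groups)
  }
  new("StudyDesign", groups = as.character(groups),
      conditions = as.character(conditions), subjects = subjects)
}

#' LatentVariable: one component of a task-PLS decomposition
#'
#' @slot singularValue covariance strength captured by the LV.
#' @slot designSaliences unit-norm weight per group x condition cell,
#'   named `"group.condition"`.
#' @slot featureSaliences unit-norm weight per channel x feature column.
#' @slot permP permutation probability (NA before inference).
#' @slot bootstrapRatios salience / bootstrap SE per column (NA before
#'   inference; individual entries may be NaN where the SE degenerated).
#' @slot threshold bootstrap-ratio stability threshold (default 2).
#' @export
setClass("LatentVariable",
  representation(
    singularValue = "numeric",
    designSaliences = "numeric",
    featureSaliences = "numeric",
    permP = "numeric",
    bootstrapRatios = "numeric",
    threshold = "numeric"
  ),
  prototype(permP = NA_real_, bootstrapRatios = NA_real_, threshold = 2)
)

setValidity("LatentVariable", function(object) {
  if (object@singularValue < 0) return("singularValue must be >= 0")
  if (abs(sqrt(sum(object@designSaliences^2)) - 1) > 1e-6) return("designSaliences must be unit-norm")
  if (abs(sqrt(sum(object@featureSaliences^2)) - 1) > 1e-6) return("featureSaliences must be unit-norm")
  if (!is.na(object@permP) && (object@permP <= 0 || object@permP > 1)) return("permP must lie in (0, 1]")
  TRUE
})

#' PlsResult: a full mean-centered task-PLS analysis
#'
#' @slot lvs list of [LatentVariable-class], ordered by decreasing
#'   singular value.
#' @slot design the [StudyDesign-class] analysed.
#' @slot X the rows x features data matrix.
#' @slot featureInfo data.frame mapping matrix columns back to
#'   channel / feature-axis coordinates.
#' @slot nPerm,nBoot resampling counts used (0 if not run).
#' @slot seed seed used for inference.
#' @export
setClass("PlsResult",
  representation(
    lvs = "list",
    design = "StudyDesign",
    X = "matrix",
    featureInfo = "data.frame",
    nPerm = "integer",
    nBoot = "integer",
    seed = "integer"
  )
)

#' SynthProfile: generative parameters for one group x condition cell
#'
#' @slot spectralSlope exponent alpha of the 1/f^alpha background.
#' @slot bandComponents data.frame with columns `centerHz`, `bandwidthHz`,
#'   `relativeAmplitude` (amplitude of each band-limited oscillation
#'   relative to the unit-SD background).
#' @slot backgroundSd SD of the 1/f background in uV (0 disables it).
#' @slot noiseSd white measurement-noise SD in uV.
#' @slot artifactRate fraction of epochs to contaminate, in [0, 1].
#' @slot artifactAmplitude peak amplitude of the injected transient in uV.
#' @export
setClass("SynthProfile",
  representation(
    spectralSlope = "numeric",
    bandComponents = "data.frame",
    backgroundSd = "numeric",
    noiseSd = "numeric",
    artifactRate = "numeric",
    artifactAmplitude = "numeric"
  )
)

setValidity("SynthProfile", function(object) {
  b <- object@bandComponents
  need <- c("centerHz", "bandwidthHz", "relativeAmplitude")
  if (nrow(b) && !all(need %in% names(b))) return("bandComponents needs centerHz, bandwidthHz, relativeAmplitude")
  if (nrow(b)) {
    if (any(b$relativeAmplitude < 0)) return("relativeAmplitude must be >= 0")
    if (any(b$bandwidthHz <= 0)) return("bandwidthHz must be > 0")
  }
  if (object@spectralSlope < 0) return("spectralSlope must be >= 0")
  if (object@artifactRate < 0 || object@artifactRate > 1) return("artifactRate must lie in [0, 1]")
  if (object@backgroundSd < 0 || object@noiseSd < 0) return("SDs must be >= 0")
  TRUE
})

#' @rdname SynthProfile-class
#' @param spectralSlope,backgroundSd,noiseSd,artifactRate,artifactAmplitude
#'   see slot documentation.
#' @param bandComponents data.frame of oscillatory components, or NULL.
#' @return A `SynthProfile` object.
#' @export
synthProfile <- function(spectralSlope = 1.3, bandComponents = NULL,
                         backgroundSd = 5, noiseSd = 0.5,
                         artifactRate = 0, artifactAmplitude = 150) {
  if (is.null(bandComponents)) {
    bandComponents <- data.frame(centerHz = numeric(0), bandwidthHz = numeric(0),
                                 relativeAmplitude = numeric(0))
  }
  new("SynthProfile", spectralSlope = spectralSlope,
      bandComponents = as.data.frame(bandComponents),
      backgroundSd = backgroundSd, noiseSd = noiseSd,
      artifactRate = artifactRate, artifactAmplitude = artifactAmplitude)
}

#' SynthStudySpec: full layout of a synthetic study
#'
#' @slot design the [StudyDesign-class] (groups, conditions, subjects).
#' @slot profiles named list mapping `"group.condition"` to
#'   [SynthProfile-class]; every cell must be present.
#' @slot nEpochs epochs per recording.
#' @slot epochMs epoch duration (ms).
#' @slot fs sampling rate (Hz).
#' @slot channels channel labels.
#' @slot subjectSdFrac SD of the subject-level random scaling of band
#'   amplitudes, as a fraction of the mean (default 0.10).
#' @slot seed integer; fully determines the generated study.
#' @export
setClass("SynthStudySpec",
  representation(
    design = "StudyDesign",
    profiles = "list",
    nEpochs = "integer",
    epochMs = "numeric",
    fs = "numeric",
    channels = "character",
    subjectSdFrac = "numeric",
    seed = "integer"
  )
)

setValidity("SynthStudySpec", function(object) {
  cells <- as.vector(outer(object@design@groups, object@design@conditions, paste, sep = "."))
  if (!all(cells %in% names(object@profiles)))
    return(paste("missing profile for cell(s):",
                 paste(setdiff(cells, names(object@profiles)), collapse = ", ")))
  ns <- object@epochMs * object@fs / 1000
  if (abs(ns - round(ns)) > 1e-9) return("epochMs * fs / 1000 must be an integer")
  nyq <- object@fs / 2
  for (p in object@profiles) {
    if (nrow(p@bandComponents) && any(p@bandComponents$centerHz >= nyq))
      return("all band centers must lie below the Nyquist frequency")
  }
  if (object@nEpochs < 1L) return("nEpochs must be >= 1")
  TRUE
})

#' @rdname SynthStudySpec-class
#' @param design,profiles,nEpochs,epochMs,fs,channels,subjectSdFrac,seed see
#'   slot documentation.
#' @return A `SynthStudySpec` object.
#' @export
synthStudySpec <- function(design, profiles, nEpochs = 48L, epochMs = 2500,
                           fs = 1000, channels = fullMontage(),
                           subjectSdFrac = 0.10, seed = 1L) {
  new("SynthStudySpec", design = design, profiles = profiles,
      nEpochs = as.integer(nEpochs), epochMs = epochMs, fs = fs,
      channels = channels, subjectSdFrac = subjectSdFrac,
      seed = as.integer(seed))
}
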