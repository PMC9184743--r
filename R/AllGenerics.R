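#' Accessors for restdyn objects
#'
#' Small accessor generics so user code never touches slots directly:
#' `epochData()` returns the epochs x channels x samples array,
#' `samplingRate()` the sampling rate in Hz, `channelLabels()` the channel
#' labels, `epochDuration()` the epoch length in ms, `nEpochs()` /
#' `nChannels()` / `nSamples()` the array dimensions, `provenance()` the
#' processing log, `gridValues()` a FeatureGrid's channels x features
#' matrix, `featureValues()` its feature-axis values, and `latentVariables()`
#' the list of latent variables of a PLS result.
#'
#' @param x a restdyn object.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("epochDuration", function(x) standardGeneric("epochDuration"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("latentVariables", function(x) standardGeneric("latentVariables"))

#' @rdname accessors
setMethod("epochData", "EpochedRecording", function(x) x@data)
#' @rdname accessors
setMethod("samplingRate", "EpochedRecording", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "EpochedRecording", function(x) x@channelLabels)
#' @rdname accessors
setMethod("epochDuration", "EpochedRecording", function(x) x@epochMs)
#' @rdname accessors
setMethod("nEpochs", "EpochedRecording", function(x) dim(x@data)[1])
#' @rdname accessors
setMethod("nChannels", "EpochedRecording", function(x) dim(x@data)[2])
#' @rdname accessors
setMethod("nSamples", "EpochedRecording", function(x) dim(x@data)[3])
#' @rdname accessors
setMethod("provenance", "EpochedRecording", function(x) x@provenance)

#' @rdname accessors
setMethod("gridValues", "FeatureGrid", function(x) x@values)
#' @rdname accessors
setMethod("channelLabels", "FeatureGrid", function(x) x@channelLabels)
#' @rdname accessors
setMethod("featureValues", "FeatureGrid", function(x) x@featureValues)

#' @rdname accessors
setMethod("latentVariables", "PlsResult", function(x) x@lvs)

setMethod("show", "EpochedRecording", function(object) {
  cat(sprintf("EpochedRecording: %d epochs x %d channels x %d samples (%g ms @ %g Hz)\n",
              nEpochs(object), nChannels(object), nSamples(object),
              object@epochMs, object@fs))
  cat("channels:", paste(head(object@channelLabels, 8), collapse = " "),
      if (nChannels(object) > 8) "..." else "", "\n")
  if (length(object@provenance))
    cat("provenance:", paste(object@provenance, collapse = "; "), "\n")
})

setMethod("show", "RejectionReport", function(object) {
  cat(sprintf("RejectionReport: %d of %d epochs rejected at %g uV peak-to-peak\n",
              object@nRejected, object@nInput, object@thresholdUv))
  if (object@nRejected)
    cat("rejected:", paste(object@rejectedIndices, collapse = " "), "\n")
})

setMethod("show", "FeatureGrid", function(object) {
  cat(sprintf("%s: %d channels x %d features\n", class(object),
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d group(s) x %d condition(s), %d subjects\n",
              length(object@groups), length(object@conditions),
              length(unlist(object@subjects))))
  cat("groups:", paste(object@groups, collapse = " "), "\n")
  cat("conditions:", paste(object@conditions, collapse = " "), "\n")
})

setMethod("show", "LatentVariable", function(object) {
  cat(sprintf("LatentVariable: s = %.4g, perm p = %s\n", object@singularValue,
              ifelse(is.na(object@permP), "not assessed", format.pval(object@permP))))
})

setMethod("show", "PlsResult", function(object) {
  s <- vapply(object@lvs, function(l) l@singularValue, 0)
  pct <- 100 * s^2 / sum(s^2)
  cat(sprintf("PlsResult: %d latent variable(s) over %d rows x %d features\n",
              length(object@lvs), nrow(object@X), ncol(object@X)))
  for (k in seq_along(object@lvs)) {
    lv <- object@lvs[[k]]
    cat(sprintf("  LV%d: s = %.4g (%.1f%% covariance), perm p = %s\n",
                k, lv@singularValue, pct[k],
                ifelse(is.na(lv@permP), "NA", format(lv@permP, digits = 3))))
  }
})

setMethod("show", "SynthProfile", function(object) {
  cat(sprintf("SynthProfile: 1/f^%.2f background (SD %g uV), %d band component(s), noise %g uV\n",
              object@spectralSlope, object@backgroundSd,
              nrow(object@bandComponents), object@noiseSd))
  if (object@artifactRate > 0)
    cat(sprintf("  artifacts: rate %.2f, amplitude %g uV\n",
                object@artifactRate, object@artifactAmplitude))
})

setMethod("show", "SynthStudySpec", function(object) {
  cat(sprintf("SynthStudySpec: %d x %d design, %d epochs of %g ms @ %g Hz, %d channels, seed %d\n",
              length(object@design@groups), length(object@design@conditions),
              object@nEpochs, object@epochMs, object@fs,
              length(object@channels), object@seed))
})
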