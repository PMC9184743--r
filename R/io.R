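# On-disk formats: the versioned epoched container (JSON-text header +
# little-endian float64 payload), a minimal continuous EDF reader/writer,
# a plain CSV fallback for continuous data, and TSV/JSON writers for grids,
# rejection reports and PLS results.

CONTAINER_VERSION <- 1L

#' Write / read the epoched on-disk container
#'
#' One file per subject-condition: a single JSON header line (format
#' version, dimensions, sampling rate, epoch duration, channel labels,
#' provenance, metadata) followed by the epochs x channels x samples array
#' as little-endian float64 in R array order. EDF cannot store epoch
#' structure losslessly, hence this container.
#'
#' @param rec an [EpochedRecording-class].
#' @param path file path.
#' @return `writeEpochs()` returns `path` invisibly; `readEpochs()` the
#'   reconstructed [EpochedRecording-class].
#' @export
writeEpochs <- function(rec, path) {
  header <- list(
    format = "restdyn-epochs", version = CONTAINER_VERSION,
    dim = dim(rec@data), fs = rec@fs, epochMs = rec@epochMs,
    channels = rec@channelLabels, provenance = rec@provenance,
    artifactEpochs = rec@metadata$artifactEpochs)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(jsonlite::toJSON(header, auto_unbox = TRUE,
                                             digits = NA), "\n")), con)
  writeBin(as.vector(rec@data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header = bytes up to the first newline
  buf <- raw(0)
  repeat {
    chunk <- readBin(con, "raw", n = 65536L)
    if (!length(chunk)) stop("malformed container: no header terminator")
    nl <- match(as.raw(10L), chunk)
    if (!is.na(nl)) {
      buf <- c(buf, chunk[seq_len(nl - 1L)])
      seek(con, where = length(buf) + 1L, origin = "start")
      break
    }
    buf <- c(buf, chunk)
  }
  header <- jsonlite::fromJSON(rawToChar(buf))
  if (!identical(header$format, "restdyn-epochs"))
    stop("not a restdyn epoched container: ", path)
  if (header$version > CONTAINER_VERSION)
    stop("container version ", header$version, " is newer than supported")
  d <- header$dim
  vals <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  if (length(vals) != prod(d)) stop("truncated container payload")
  md <- list()
  if (!is.null(header$artifactEpochs))
    md$artifactEpochs <- as.integer(header$artifactEpochs)
  new("EpochedRecording", data = array(vals, dim = d),
      fs = as.numeric(header$fs), epochMs = as.numeric(header$epochMs),
      channelLabels = as.character(header$channels),
      provenance = as.character(header$provenance), metadata = md)
}

padField <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write / read continuous multichannel data as EDF
#'
#' Minimal European Data Format support for continuous (not epoched)
#' recordings: 16-bit samples, one record per second, identical sampling
#' rate on every channel. A trailing partial second is dropped on write.
#' Amplitudes are scaled per channel to the full digital range, so the
#' round-trip is exact to about 1e-4 of the channel's amplitude range.
#'
#' @param signal channels x samples matrix (uV); rownames used as labels.
#' @param fs sampling rate in Hz (integer).
#' @param path file path.
#' @return `writeEdf()` returns `path` invisibly; `readEdf()` a list with
#'   `signal` (channels x samples, labeled rows) and `fs`.
#' @export
writeEdf <- function(signal, fs, path) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  fs <- as.integer(round(fs))
  ns <- nrow(signal)
  nRec <- ncol(signal) %/% fs
  if (nRec < 1) stop("signal shorter than one 1-s record")
  labels <- rownames(signal)
  if (is.null(labels)) labels <- sprintf("ch%d", seq_len(ns))
  physMin <- apply(signal, 1, min)
  physMax <- apply(signal, 1, max)
  flat <- physMax - physMin == 0
  physMax[flat] <- physMin[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8), padField("X X X X", 80), padField("Startdate X X X X", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * (1 + ns), 8), padField("", 44),
    padField(nRec, 8), padField("1", 8), padField(ns, 8))
  sig <- paste0(
    paste(padField(labels, 16), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(padField("uV", 8), ns), collapse = ""),
    paste(padField(sprintf("%.6g", physMin), 8), collapse = ""),
    paste(padField(sprintf("%.6g", physMax), 8), collapse = ""),
    paste(rep(padField("-32768", 8), ns), collapse = ""),
    paste(rep(padField("32767", 8), ns), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(padField(fs, 8), ns), collapse = ""),
    paste(rep(padField("", 32), ns), collapse = ""))
  writeBin(charToRaw(paste0(hdr, sig)), con)
  scale <- (physMax - physMin) / 65535
  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((signal[ch, idx] - physMin[ch]) / scale[ch]) - 32768)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

readAscii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n = n)))

#' @rdname writeEdf
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readAscii(con, 8)                         # version
  readAscii(con, 80); readAscii(con, 80)    # patient, recording ids
  readAscii(con, 8); readAscii(con, 8)      # date, time
  readAscii(con, 8)                         # header bytes
  readAscii(con, 44)                        # reserved
  nRec <- as.integer(readAscii(con, 8))
  recDur <- as.numeric(readAscii(con, 8))
  ns <- as.integer(readAscii(con, 8))
  labels <- vapply(seq_len(ns), function(i) readAscii(con, 16), "")
  for (i in seq_len(ns)) readAscii(con, 80) # transducer
  for (i in seq_len(ns)) readAscii(con, 8)  # physical dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(readAscii(con, 8)), 0)
  physMax <- vapply(seq_len(ns), function(i) as.numeric(readAscii(con, 8)), 0)
  digMin <- vapply(seq_len(ns), function(i) as.numeric(readAscii(con, 8)), 0)
  digMax <- vapply(seq_len(ns), function(i) as.numeric(readAscii(con, 8)), 0)
  for (i in seq_len(ns)) readAscii(con, 80) # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(readAscii(con, 8)), 0L)
  for (i in seq_len(ns)) readAscii(con, 32) # reserved
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1] / recDur
  out <- matrix(0, ns, nRec * spr[1])
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      out[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        (dig - digMin[ch]) * scale[ch] + physMin[ch]
    }
  }
  rownames(out) <- labels
  list(signal = out, fs = fs)
}

#' Read continuous data from the plain CSV fallback
#'
#' Samples x channels with a header row of channel labels.
#'
#' @param path file path.
#' @return channels x samples matrix with labels as rownames.
#' @export
readContinuousCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  t(as.matrix(df))
}

#' Write a feature grid as TSV with a JSON sidecar
#'
#' Rows = channels, columns = feature-axis values (scales, Hz bins or
#' timepoints); the sidecar (`<path>.json`) records the class, feature
#' axis, epoch counts and, for entropy grids, the parameters used.
#'
#' @param grid a [FeatureGrid-class].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeGrid <- function(grid, path) {
  v <- gridValues(grid)
  df <- data.frame(channel = channelLabels(grid), v, check.names = FALSE)
  colnames(df) <- c("channel", featureValues(grid))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(class = as.character(class(grid)),
               featureValues = featureValues(grid),
               nEpochsAveraged = grid@nEpochsAveraged)
  if (is(grid, "MseGrid"))
    side$params <- list(m = grid@params@m, rFrac = grid@params@rFrac,
                        maxScale = grid@params@maxScale,
                        minCoarseSamples = grid@params@minCoarseSamples)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a rejection report as TSV
#'
#' @param report a [RejectionReport-class].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeRejectionReport <- function(report, path) {
  df <- data.frame(
    nInput = report@nInput, nRejected = report@nRejected,
    thresholdUv = report@thresholdUv,
    rejectedIndices = paste(report@rejectedIndices, collapse = ","))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a PLS result as TSV maps plus a JSON summary
#'
#' Per latent variable: the design-salience table (TSV), the feature
#' saliences and bootstrap-ratio maps un-flattened to channel x feature
#' TSVs, and a scalar summary (singular value, % covariance, permutation
#' p) in `pls_summary.json`.
#'
#' @param result a [PlsResult-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePlsReport <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- vapply(result@lvs, function(l) l@singularValue, 0)
  pct <- 100 * s^2 / sum(s^2)
  summary <- lapply(seq_along(result@lvs), function(k) {
    lv <- result@lvs[[k]]
    list(lv = k, singularValue = lv@singularValue, pctCovariance = pct[k],
         permP = lv@permP, threshold = lv@threshold)
  })
  jsonlite::write_json(
    list(nPerm = result@nPerm, nBoot = result@nBoot, seed = result@seed,
         lvs = summary),
    file.path(dir, "pls_summary.json"), auto_unbox = TRUE, digits = NA)
  for (k in seq_along(result@lvs)) {
    lv <- result@lvs[[k]]
    ds <- data.frame(cell = names(lv@designSaliences),
                     salience = unname(lv@designSaliences))
    utils::write.table(ds, file.path(dir, sprintf("lv%d_design_saliences.tsv", k)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (what in c("featureSaliences", "bootstrapRatios")) {
      m <- salienceMap(result, k, what)
      df <- data.frame(channel = rownames(m), m, check.names = FALSE)
      fname <- sprintf("lv%d_%s.tsv", k,
                       ifelse(what == "featureSaliences", "feature_saliences",
                              "bootstrap_ratios"))
      utils::write.table(df, file.path(dir, fname), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}
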