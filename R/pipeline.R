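# End-to-end orchestration (ingest -> preprocess -> MSE/SPD -> PLS ->
# reports) plus the small summary-statistics helpers used for participant
# tables.

#' Run configuration
#'
#' Validates and freezes the settings of one end-to-end run. Defaults equal
#' the study settings: 2500 ms epochs, 100 uV rejection, 500 permutations,
#' 500 bootstrap samples, bootstrap-ratio threshold 2.0.
#'
#' @param manifest data.frame with columns `group`, `condition`, `subject`,
#'   `path` (epoched-container files, or channel x timepoint TSVs for
#'   `kind = "erp-grid"`).
#' @param kind analysis kind: `"mse"`, `"spd"` or `"erp-grid"`.
#' @param outDir output directory.
#' @param epochMs,rejectUv preprocessing parameters.
#' @param channels channel subset applied after rejection (NULL keeps all).
#' @param mseParams an [MseParams-class] (kind = "mse").
#' @param rangeHz spectral analysis range (kind = "spd").
#' @param bands band set for the band-summary output (kind = "spd").
#' @param nPerm,nBoot,threshold,seed PLS inference settings.
#' @return A validated `runConfig` list (class `"runConfig"`).
#' @export
runConfig <- function(manifest, kind = c("mse", "spd", "erp-grid"),
                      outDir = tempfile("restdyn_run_"),
                      epochMs = 2500, rejectUv = 100, channels = NULL,
                      mseParams = restdyn::mseParams(), rangeHz = c(0.4, 40),
                      bands = defaultBands(), nPerm = 500, nBoot = 500,
                      threshold = 2, seed = 1L) {
  kind <- match.arg(kind)
  need <- c("group", "condition", "subject", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  groups <- unique(manifest$group)
  conditions <- unique(manifest$condition)
  for (g in groups) {
    subj <- unique(manifest$subject[manifest$group == g])
    for (cn in conditions) {
      have <- manifest$subject[manifest$group == g & manifest$condition == cn]
      miss <- setdiff(subj, have)
      if (length(miss))
        stop(sprintf("manifest missing cell (%s, %s, %s)", g, cn, miss[1]))
    }
  }
  missingFiles <- manifest$path[!file.exists(manifest$path)]
  if (length(missingFiles))
    stop("unresolvable path(s): ", paste(missingFiles, collapse = ", "))
  structure(list(manifest = manifest, kind = kind, outDir = outDir,
                 epochMs = epochMs, rejectUv = rejectUv, channels = channels,
                 mseParams = mseParams, rangeHz = rangeHz, bands = bands,
                 nPerm = nPerm, nBoot = nBoot, threshold = threshold,
                 seed = as.integer(seed)),
            class = "runConfig")
}

#' Run a full analysis from a manifest
#'
#' Executes preprocess (rejection, then channel subsetting) -> feature
#' extraction -> task PLS, writing per-subject grids, rejection reports,
#' LV tables/maps and a provenance log under `config$outDir`. Stage errors
#' are surfaced with the (group, condition, subject) context.
#'
#' @param config a [runConfig()].
#' @return Invisibly, a list with `pls` (the [PlsResult-class]), `grids`,
#'   `rejections` and `outDir`.
#' @export
runStudy <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  m <- config$manifest
  design <- studyDesign(unique(m$group), unique(m$condition),
                        setNames(lapply(unique(m$group), function(g)
                          unique(m$subject[m$group == g])), unique(m$group)))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  gridDir <- file.path(config$outDir, "grids")
  dir.create(gridDir, showWarnings = FALSE)
  grids <- list()
  rejections <- list()
  for (i in seq_len(nrow(m))) {
    key <- paste(m$group[i], m$condition[i], m$subject[i], sep = ".")
    res <- tryCatch({
      if (config$kind == "erp-grid") {
        df <- utils::read.table(m$path[i], sep = "\t", header = TRUE,
                                check.names = FALSE)
        vals <- as.matrix(df[, -1, drop = FALSE])
        erpGrid(vals, times = as.numeric(colnames(vals)),
                channels = as.character(df[[1]]))
      } else {
        rec <- readEpochs(m$path[i])
        rej <- rejectEpochs(rec, config$rejectUv)
        rejections[[key]] <- rej$report
        writeRejectionReport(rej$report,
                             file.path(gridDir, paste0(key, "_rejection.tsv")))
        rec <- rej$recording
        if (!is.null(config$channels)) rec <- selectChannels(rec, config$channels)
        if (config$kind == "mse") mseGrid(rec, config$mseParams)
        else spdGrid(rec, config$rangeHz)
      }
    }, error = function(e)
      stop(sprintf("stage failed for (%s, %s, %s): %s", m$group[i],
                   m$condition[i], m$subject[i], conditionMessage(e)),
           call. = FALSE))
    grids[[key]] <- res
    writeGrid(res, file.path(gridDir, paste0(key, ".tsv")))
  }
  pls <- taskPls(grids, design, nPerm = config$nPerm, nBoot = config$nBoot,
                 seed = config$seed, threshold = config$threshold)
  writePlsReport(pls, file.path(config$outDir, "pls"))
  echo <- config
  echo$manifest <- NULL
  jsonlite::write_json(
    list(package = "restdyn",
         version = as.character(utils::packageVersion("restdyn")),
         seed = config$seed, kind = config$kind,
         config = echo[setdiff(names(echo), c("mseParams", "bands"))],
         manifest = m),
    file.path(config$outDir, "provenance.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(list(pls = pls, grids = grids, rejections = rejections,
                 outDir = config$outDir))
}

#' Analyze an in-memory synthetic study
#'
#' Convenience path used by simulations: preprocess each generated
#' recording (rejection, optional channel subset), extract MSE or SPD
#' grids, and run task PLS — without touching disk.
#'
#' @param recordings named list from [generateStudy()].
#' @param design the [StudyDesign-class] (defaults to
#'   `attr(recordings, "design")`).
#' @param kind `"mse"` or `"spd"`.
#' @param rejectUv rejection threshold (NULL skips rejection).
#' @param channels channel subset (NULL keeps all).
#' @param mseParams,rangeHz feature-extraction settings.
#' @param nPerm,nBoot,seed,... passed to [taskPls()].
#' @return A [PlsResult-class].
#' @export
analyzeStudy <- function(recordings, design = attr(recordings, "design"),
                         kind = c("mse", "spd"), rejectUv = 100,
                         channels = NULL, mseParams = restdyn::mseParams(),
                         rangeHz = c(0.4, 40), nPerm = 500, nBoot = 500,
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  grids <- lapply(recordings, function(rec) {
    if (!is.null(rejectUv)) rec <- rejectEpochs(rec, rejectUv)$recording
    if (!is.null(channels)) rec <- selectChannels(rec, channels)
    if (kind == "mse") mseGrid(rec, mseParams) else spdGrid(rec, rangeHz)
  })
  taskPls(grids, design, nPerm = nPerm, nBoot = nBoot, seed = seed, ...)
}

#' Construct an ErpGrid from a channel x timepoint matrix
#'
#' Accepts externally computed per-subject event-related averages so the
#' electrode-selection analyses run through the identical PLS engine.
#'
#' @param values channels x timepoints matrix (uV).
#' @param times timepoints in ms.
#' @param channels channel labels.
#' @return An [ErpGrid-class].
#' @export
erpGrid <- function(values, times, channels = rownames(values)) {
  if (is.null(channels)) channels <- sprintf("ch%d", seq_len(nrow(values)))
  new("ErpGrid", values = as.matrix(values), channelLabels = as.character(channels),
      featureValues = as.numeric(times),
      nEpochsAveraged = matrix(1L, nrow(values), ncol(values)))
}

#' Average epochs into an event-related potential grid
#'
#' Plumbing for the task-locked analyses: subtracts the mean of the
#' baseline interval per epoch and channel, then averages the accepted
#' epochs.
#'
#' @param rec an [EpochedRecording-class] of stimulus-locked epochs.
#' @param baselineMs `c(from, to)` in ms relative to epoch start defining
#'   the (prestimulus) baseline interval.
#' @param tZeroMs time of stimulus onset relative to epoch start (sets the
#'   timepoint axis).
#' @return An [ErpGrid-class] (channels x timepoints, uV).
#' @export
erpAverage <- function(rec, baselineMs = c(0, 100), tZeroMs = 100) {
  d <- epochData(rec)
  fs <- samplingRate(rec)
  b0 <- max(1L, as.integer(round(baselineMs[1] * fs / 1000)) + 1L)
  b1 <- as.integer(round(baselineMs[2] * fs / 1000))
  avg <- matrix(0, dim(d)[2], dim(d)[3])
  for (e in seq_len(dim(d)[1])) {
    ep <- array(d[e, , , drop = FALSE], dim = dim(d)[2:3])
    ep <- ep - rowMeans(ep[, b0:b1, drop = FALSE])
    avg <- avg + ep
  }
  avg <- avg / dim(d)[1]
  times <- (seq_len(dim(d)[3]) - 1) * 1000 / fs - tZeroMs
  erpGrid(avg, times, channelLabels(rec))
}

#' One-sample t statistic from summary statistics
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` on `n - 1` degrees of freedom, with
#' the two-sided p-value; used to reproduce participant-table comparisons
#' of group IQ means against the population mean of 100.
#'
#' @param mean,sd,n sample mean, SD and size (n >= 2, sd > 0).
#' @param mu0 null-hypothesis mean (default 100).
#' @return List with `t`, `df`, `p`.
#' @export
oneSampleTFromSummary <- function(mean, sd, n, mu0 = 100) {
  if (n < 2) stop("n must be >= 2")
  if (sd <= 0) stop("degenerate input: sd must be > 0")
  t <- (mean - mu0) / (sd / sqrt(n))
  df <- n - 1
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Main-effects (additive) two-way ANOVA F from cell summaries
#'
#' Fits the additive linear model `y ~ A + B` (no interaction) by least
#' squares to a data reconstruction matching the cells' sufficient
#' statistics (mean, SD, n); the F statistic depends only on those
#' sufficient statistics, so any reconstruction gives the same answer.
#' `df1 = levelsA - 1`, `df2 = N - 1 - (levelsA - 1) - (levelsB - 1)`.
#'
#' @param cells data.frame with columns `A`, `B` (factor levels), `mean`,
#'   `sd`, `n` — one row per cell; all cells of the A x B layout must be
#'   present.
#' @param factor which main effect to test: `"A"` or `"B"`.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
additiveTwoWayFFromCells <- function(cells, factor = "A") {
  need <- c("A", "B", "mean", "sd", "n")
  if (!all(need %in% names(cells)))
    stop("cells needs columns: ", paste(need, collapse = ", "))
  full <- expand.grid(A = unique(cells$A), B = unique(cells$B))
  key <- function(df) paste(df$A, df$B)
  if (!all(key(full) %in% key(cells)))
    stop("missing cell(s): ", paste(setdiff(key(full), key(cells)), collapse = "; "))
  # reconstruct any realization with the stated sample moments
  # (sample SD, n-1 normalizer)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$n[i]
    z <- as.vector(scale(seq_len(n)))       # mean 0, sample SD 1
    data.frame(A = cells$A[i], B = cells$B[i],
               y = cells$mean[i] + cells$sd[i] * z)
  }))
  fit <- lm(y ~ A + B, data = rows)
  an <- anova(fit)
  Fv <- an[factor, "F value"]
  list(F = Fv, df1 = an[factor, "Df"], df2 = an["Residuals", "Df"],
       p = an[factor, "Pr(>F)"])
}
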