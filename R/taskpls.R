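# Mean-centered task PLS: SVD of the group x condition cell-mean deviation
# matrix, permutation testing of latent variables, and bootstrap-ratio
# stability maps over subject feature grids.

# cell labels in row order: conditions nested within groups
cellNames <- function(design) {
  as.vector(t(outer(design@groups, design@conditions, paste, sep = ".")))
}

# row bookkeeping: subjects nested within conditions nested within groups
rowInfo <- function(design) {
  rows <- do.call(rbind, lapply(design@groups, function(g) {
    do.call(rbind, lapply(design@conditions, function(cn) {
      data.frame(group = g, condition = cn, subject = design@subjects[[g]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rows$cell <- paste(rows$group, rows$condition, sep = ".")
  rows
}

#' Build the PLS data matrix from per-subject feature grids
#'
#' Rows are ordered subjects-within-conditions-within-groups (fixed by the
#' design, not by the input list order); columns are the flattened
#' channel x feature grid (each channel's features contiguous).
#'
#' @param grids named list keyed `"group.condition.subject"` of
#'   [FeatureGrid-class] objects (or bare channels x features matrices),
#'   all with an identical layout.
#' @param design a [StudyDesign-class].
#' @return rows x features numeric matrix with attributes `rowInfo`
#'   (data.frame: group, condition, subject, cell) and `featureInfo`
#'   (data.frame: channel, feature).
#' @export
buildMatrix <- function(grids, design) {
  validObject(design)
  ri <- rowInfo(design)
  keys <- paste(ri$group, ri$condition, ri$subject, sep = ".")
  missing <- setdiff(keys, names(grids))
  if (length(missing))
    stop("missing grid for cell(s): ", paste(missing, collapse = ", "))
  asMat <- function(g) if (is(g, "FeatureGrid")) gridValues(g) else g
  first <- grids[[keys[1]]]
  fm <- asMat(first)
  if (is(first, "FeatureGrid")) {
    featureInfo <- data.frame(
      channel = rep(channelLabels(first), each = length(featureValues(first))),
      feature = rep(featureValues(first), times = nrow(fm)),
      stringsAsFactors = FALSE)
  } else {
    featureInfo <- data.frame(
      channel = rep(sprintf("ch%d", seq_len(nrow(fm))), each = ncol(fm)),
      feature = rep(seq_len(ncol(fm)), times = nrow(fm)),
      stringsAsFactors = FALSE)
  }
  X <- t(vapply(keys, function(k) {
    m <- asMat(grids[[k]])
    if (!all(dim(m) == dim(fm))) stop("grid layout mismatch at ", k)
    as.vector(t(m))
  }, numeric(nrow(fm) * ncol(fm))))
  rownames(X) <- keys
  if (anyNA(X) || any(!is.finite(X)))
    stop("feature grids must be finite everywhere (undefined entropy cells ",
         "must be resolved before PLS, e.g. by restricting scales)")
  attr(X, "rowInfo") <- ri
  attr(X, "featureInfo") <- featureInfo
  X
}

#' Mean-center the data matrix by cell
#'
#' Returns the cells x features deviation matrix M: each row is a cell's
#' subject mean minus the unweighted grand mean of the cell means, so the
#' rows of M sum to the zero vector. This is the "task PLS" centering whose
#' SVD pairs a design contrast with a brain pattern.
#'
#' @param X data matrix from [buildMatrix()] (or any matrix with a
#'   `rowInfo` attribute / explicit `cells` argument).
#' @param design a [StudyDesign-class] (used if `X` lacks `rowInfo`).
#' @param cells optional character vector assigning each row to a cell.
#' @return cells x features matrix, rows in design cell order.
#' @export
meanCenter <- function(X, design = NULL, cells = NULL) {
  if (is.null(cells)) {
    ri <- attr(X, "rowInfo")
    if (is.null(ri) && !is.null(design)) ri <- rowInfo(design)
    if (is.null(ri)) stop("need rowInfo attribute, design, or cells")
    cells <- ri$cell
  }
  lev <- unique(cells)
  cm <- t(vapply(lev, function(cl) {
    idx <- which(cells == cl)
    if (!length(idx)) stop("empty cell: ", cl)
    colMeans(X[idx, , drop = FALSE])
  }, numeric(ncol(X))))
  rownames(cm) <- lev
  sweep(cm, 2, colMeans(cm))
}

#' Extract latent variables from the deviation matrix
#'
#' Singular value decomposition of M, ordered by decreasing singular value.
#' Rank-deficient trailing components (singular value below
#' `max(dim(M)) * eps * s1`) are dropped. Sign convention: each LV's
#' feature-salience vector is flipped so its largest-magnitude element is
#' positive; the design saliences flip jointly, leaving the reconstruction
#' unchanged.
#'
#' @param M cells x features matrix from [meanCenter()].
#' @return List with `d` (singular values), `u` (cells x K design
#'   saliences), `v` (features x K feature saliences).
#' @export
extractLvs <- function(M) {
  if (anyNA(M) || any(!is.finite(M))) stop("M must be finite")
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * max(sv$d, 0)
  K <- sum(sv$d > tol)
  K <- max(K, 1L)
  d <- sv$d[seq_len(K)]
  u <- sv$u[, seq_len(K), drop = FALSE]
  v <- sv$v[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    i <- which.max(abs(v[, k]))
    if (v[i, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  rownames(u) <- rownames(M)
  list(d = d, u = u, v = v)
}

# rebuild X rows for one permutation: subjects (with all their condition
# rows) are reassigned across group slots without replacement, and condition
# labels are shuffled within each subject
permuteRows <- function(ri, nCond) {
  subj <- unique(ri$subject)
  nSubj <- length(subj)
  slotOf <- split(seq_len(nrow(ri)), ri$subject)  # rows of each subject, design order
  # order rows of each subject by condition index
  condIdx <- as.integer(factor(ri$condition, levels = unique(ri$condition)))
  slotOf <- lapply(slotOf, function(idx) idx[order(condIdx[idx])])
  assign <- sample(nSubj)                          # slot s gets subject assign[s]
  newRows <- integer(nrow(ri))
  for (s in seq_len(nSubj)) {
    dst <- slotOf[[subj[s]]]                       # destination slot rows
    src <- slotOf[[subj[assign[s]]]]               # source subject rows
    newRows[dst] <- src[sample(nCond)]             # shuffle condition labels
  }
  newRows
}

#' Permutation test of the latent variables
#'
#' Each permutation reassigns whole subjects (all their condition rows
#' together) across groups without replacement and shuffles condition
#' labels within each subject, recomputes the mean-centered SVD, and
#' compares singular values LV-by-LV by rank (`mode = "rank"`, default) or
#' after Procrustes rotation of the permuted decomposition onto the
#' original one (`mode = "procrustes"`). p-values use the add-one Monte
#' Carlo estimator `(1 + #exceedances) / (1 + nPerm)` and so are never 0.
#'
#' @param X data matrix from [buildMatrix()].
#' @param design a [StudyDesign-class] (only needed if `X` lacks rowInfo).
#' @param nPerm number of permutations (study default 500).
#' @param seed integer seed; results are deterministic given it.
#' @param mode singular-value comparison mode.
#' @return List with `permP` (one p per LV) and `obs` (observed singular
#'   values).
#' @export
permutationTest <- function(X, design = NULL, nPerm = 500, seed = 1L,
                            mode = c("rank", "procrustes")) {
  mode <- match.arg(mode)
  ri <- attr(X, "rowInfo")
  if (is.null(ri)) ri <- rowInfo(design)
  if (nPerm < 19)
    warning("nPerm too small to resolve alpha = 0.05; p-values will be coarse")
  obs <- extractLvs(meanCenter(X, cells = ri$cell))
  K <- length(obs$d)
  nCond <- length(unique(ri$condition))
  exceed <- numeric(K)
  set.seed(deriveSeed(seed, 7919L))
  for (p in seq_len(nPerm)) {
    Xp <- X[permuteRows(ri, nCond), , drop = FALSE]
    lvp <- extractLvs(meanCenter(Xp, cells = ri$cell))
    sp <- if (mode == "rank") {
      lvp$d
    } else {
      # Procrustes: rotate the permuted decomposition onto the original
      # feature saliences, then take column norms of the rotated scores
      Kp <- min(K, length(lvp$d))
      N <- crossprod(obs$v[, seq_len(Kp), drop = FALSE],
                     lvp$v[, seq_len(Kp), drop = FALSE])
      sv <- svd(N)
      R <- sv$v %*% t(sv$u)
      Tm <- lvp$u[, seq_len(Kp), drop = FALSE] %*%
        diag(lvp$d[seq_len(Kp)], Kp, Kp) %*% R
      sqrt(colSums(Tm^2))
    }
    kk <- min(K, length(sp))
    exceed[seq_len(kk)] <- exceed[seq_len(kk)] + (sp[seq_len(kk)] >= obs$d[seq_len(kk)])
  }
  list(permP = (1 + exceed) / (1 + nPerm), obs = obs$d)
}

#' Bootstrap-ratio stability of the feature saliences
#'
#' Each bootstrap resamples subject ids with replacement independently
#' within each group (a subject carries all its condition rows), recomputes
#' the mean-centered SVD, aligns the bootstrap feature saliences to the
#' original LVs (orthogonal Procrustes rotation by default, or per-LV sign
#' alignment) — the one place rotation is required, since unaligned sign
#' flips would inflate the SEs to meaninglessness — and accumulates the
#' per-element standard error. The bootstrap ratio is the original salience
#' divided by that SE; elements with zero SE return NaN with a logged count.
#'
#' @param X data matrix from [buildMatrix()].
#' @param design a [StudyDesign-class] (only needed if `X` lacks rowInfo).
#' @param nBoot number of bootstrap samples (study default 500); >= 2.
#' @param seed integer seed.
#' @param align alignment of each bootstrap decomposition to the original.
#' @return List with `ratios` (features x K matrix), `se` (same shape), and
#'   `nDegenerate` (count of zero-SE elements).
#' @export
bootstrapSaliences <- function(X, design = NULL, nBoot = 500, seed = 1L,
                               align = c("procrustes", "sign")) {
  align <- match.arg(align)
  if (nBoot < 2) stop("nBoot must be >= 2")
  ri <- attr(X, "rowInfo")
  if (is.null(ri)) ri <- rowInfo(design)
  groups <- unique(ri$group)
  if (any(vapply(groups, function(g) length(unique(ri$subject[ri$group == g])), 0L) < 2))
    stop("each group needs at least 2 subjects to bootstrap")
  obs <- extractLvs(meanCenter(X, cells = ri$cell))
  K <- length(obs$d)
  nF <- ncol(X)
  subjRows <- split(seq_len(nrow(ri)), ri$subject)
  groupSubj <- lapply(groups, function(g) unique(ri$subject[ri$group == g]))
  names(groupSubj) <- groups
  acc <- array(0, dim = c(nF, K, nBoot))
  set.seed(deriveSeed(seed, 104729L))
  for (b in seq_len(nBoot)) {
    newRows <- integer(nrow(ri))
    for (g in groups) {
      ids <- groupSubj[[g]]
      draw <- ids[sample.int(length(ids), length(ids), replace = TRUE)]
      for (s in seq_along(ids)) {
        dst <- subjRows[[ids[s]]]
        src <- subjRows[[draw[s]]]
        newRows[dst] <- src
      }
    }
    lvb <- extractLvs(meanCenter(X[newRows, , drop = FALSE], cells = ri$cell))
    Kb <- min(K, length(lvb$d))
    Vb <- lvb$v[, seq_len(Kb), drop = FALSE]
    if (align == "procrustes") {
      N <- crossprod(obs$v[, seq_len(Kb), drop = FALSE], Vb)
      sv <- svd(N)
      Vb <- Vb %*% (sv$v %*% t(sv$u))
    } else {
      for (k in seq_len(Kb)) {
        if (crossprod(obs$v[, k], Vb[, k])[1] < 0) Vb[, k] <- -Vb[, k]
      }
    }
    acc[, seq_len(Kb), b] <- Vb
  }
  se <- apply(acc, c(1, 2), stats::sd)
  ratios <- obs$v / se
  nDeg <- sum(se == 0)
  if (nDeg > 0) {
    ratios[se == 0] <- NaN
    warning(sprintf("%d degenerate (zero-SE) bootstrap element(s); NaN returned", nDeg))
  }
  list(ratios = ratios, se = se, nDegenerate = nDeg)
}

#' Mean-centered task PLS with permutation and bootstrap inference
#'
#' The full analysis: build (or accept) the data matrix, mean-center by
#' group x condition cell, decompose by SVD, assess each latent variable by
#' permutation, and map feature-salience stability by bootstrap ratios.
#' Defaults follow the study settings: 500 permutations, 500 bootstrap
#' samples, bootstrap-ratio threshold 2.0.
#'
#' @param grids named list of per-subject [FeatureGrid-class] objects keyed
#'   `"group.condition.subject"`, or a prebuilt matrix from [buildMatrix()].
#' @param design a [StudyDesign-class].
#' @param nPerm,nBoot resampling counts; set to 0 to skip that stage.
#' @param seed integer seed for both resampling schemes.
#' @param threshold bootstrap-ratio stability threshold stored on each LV.
#' @param permMode see [permutationTest()].
#' @param bootAlign see [bootstrapSaliences()].
#' @return A [PlsResult-class].
#' @export
taskPls <- function(grids, design, nPerm = 500, nBoot = 500, seed = 1L,
                    threshold = 2, permMode = c("rank", "procrustes"),
                    bootAlign = c("procrustes", "sign")) {
  permMode <- match.arg(permMode)
  bootAlign <- match.arg(bootAlign)
  X <- if (is.matrix(grids)) grids else buildMatrix(grids, design)
  ri <- attr(X, "rowInfo")
  if (is.null(ri)) {
    ri <- rowInfo(design)
    attr(X, "rowInfo") <- ri
  }
  fi <- attr(X, "featureInfo")
  if (is.null(fi))
    fi <- data.frame(channel = "all", feature = seq_len(ncol(X)))
  obs <- extractLvs(meanCenter(X, cells = ri$cell))
  K <- length(obs$d)
  permP <- rep(NA_real_, K)
  if (nPerm > 0) permP <- permutationTest(X, nPerm = nPerm, seed = seed,
                                          mode = permMode)$permP
  ratios <- matrix(NA_real_, ncol(X), K)
  if (nBoot > 0) ratios <- bootstrapSaliences(X, nBoot = nBoot, seed = seed,
                                              align = bootAlign)$ratios
  lvs <- lapply(seq_len(K), function(k) {
    new("LatentVariable",
        singularValue = obs$d[k],
        designSaliences = setNames(obs$u[, k], rownames(obs$u)),
        featureSaliences = obs$v[, k],
        permP = permP[k],
        bootstrapRatios = ratios[, k],
        threshold = threshold)
  })
  new("PlsResult", lvs = lvs, design = design, X = X, featureInfo = fi,
      nPerm = as.integer(nPerm), nBoot = as.integer(nBoot),
      seed = as.integer(seed))
}

#' Project rows of the data matrix onto a latent variable
#'
#' Row score = row vector . feature saliences; the per-subject "brain
#' score" used for bar-graph style summaries of an LV.
#'
#' @param X data matrix (rows x features).
#' @param lv a [LatentVariable-class] from the same analysis.
#' @return Numeric vector of one score per row.
#' @export
projectBrainScores <- function(X, lv) {
  if (ncol(X) != length(lv@featureSaliences))
    stop("dimension mismatch: X has ", ncol(X), " columns but the LV has ",
         length(lv@featureSaliences), " feature saliences")
  drop(X %*% lv@featureSaliences)
}

#' Un-flatten an LV map back to channels x features
#'
#' @param result a [PlsResult-class].
#' @param lv which latent variable (default 1).
#' @param what `"bootstrapRatios"` or `"featureSaliences"`.
#' @return channels x features matrix (rows = channels, columns labeled by
#'   the feature-axis values).
#' @export
salienceMap <- function(result, lv = 1L,
                        what = c("bootstrapRatios", "featureSaliences")) {
  what <- match.arg(what)
  v <- slot(result@lvs[[lv]], what)
  fi <- result@featureInfo
  chans <- unique(fi$channel)
  feats <- unique(fi$feature)
  m <- matrix(v, nrow = length(chans), ncol = length(feats), byrow = TRUE,
              dimnames = list(chans, feats))
  m
}
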