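# random grids for a complete design
randomGrids <- function(design, nChan = 2, nFeat = 2, seed = 1, shift = NULL) {
  set.seed(seed)
  grids <- list()
  for (g in design@groups) for (cn in design@conditions)
    for (s in design@subjects[[g]]) {
      m <- matrix(rnorm(nChan * nFeat), nChan, nFeat)
      if (!is.null(shift)) m <- m + shift(g, cn)
      grids[[paste(g, cn, s, sep = ".")]] <- m
    }
  grids
}

test_that("buildMatrix orders rows by design and flags missing cells", {
  design <- studyDesign(c("g1", "g2"), c("c1", "c2"), 3)
  grids <- randomGrids(design, 2, 2, seed = 1)
  X <- buildMatrix(grids, design)
  expect_equal(dim(X), c(12, 4))
  ri <- attr(X, "rowInfo")
  # subjects nested within conditions nested within groups
  expect_equal(ri$group, rep(c("g1", "g2"), each = 6))
  expect_equal(ri$condition, rep(rep(c("c1", "c2"), each = 3), 2))
  # round-trip: the row for a cell holds that subject's flattened grid
  key <- "g2.c1.g2_s02"
  i <- which(rownames(X) == key)
  expect_equal(X[i, ], as.vector(t(grids[[key]])), ignore_attr = TRUE)

  # input order does not matter
  X2 <- buildMatrix(rev(grids), design)
  expect_equal(X2, X)

  grids$g1.c1.g1_s01 <- NULL
  expect_error(buildMatrix(grids, design), "g1.c1.g1_s01")
})

test_that("mean-centering removes the unweighted grand mean of cell means", {
  design <- studyDesign(c("a", "b"), "c1", 4)
  # identical subjects -> zero deviation matrix
  grids <- randomGrids(design, 1, 3, seed = 2)
  for (k in names(grids)) grids[[k]] <- matrix(c(1, 2, 3), 1, 3)
  M0 <- meanCenter(buildMatrix(grids, design))
  expect_equal(unname(M0), matrix(0, 2, 3))

  # cells at +d and -d
  d <- c(1, -2, 0.5)
  grids2 <- randomGrids(design, 1, 3, seed = 3,
                        shift = function(g, cn) {
                          matrix(if (g == "a") d else -d, 1, 3, byrow = TRUE)
                        })
  for (k in names(grids2)) {
    g <- sub("\\..*", "", k)
    grids2[[k]] <- matrix(if (g == "a") d else -d, 1, 3)
  }
  M <- meanCenter(buildMatrix(grids2, design))
  expect_equal(M["a.c1", ], d, ignore_attr = TRUE)
  expect_equal(M["b.c1", ], -d, ignore_attr = TRUE)

  # rows always sum to the zero vector
  grids3 <- randomGrids(design, 2, 4, seed = 4)
  M3 <- meanCenter(buildMatrix(grids3, design))
  expect_equal(unname(colSums(M3)), rep(0, 8))
  expect_error(meanCenter(matrix(1, 2, 2)), "rowInfo")
})

test_that("extractLvs matches SVD identities and the eigen oracle", {
  set.seed(5)
  # rank-1 reconstruction
  u <- c(1, -1) / sqrt(2)
  v <- rnorm(6); v <- v / sqrt(sum(v^2))
  M1 <- 3 * outer(u, v)
  lv1 <- extractLvs(M1)
  expect_equal(lv1$d[1], 3)
  expect_equal(abs(sum(lv1$v[, 1] * v)), 1)
  expect_equal(abs(sum(lv1$u[, 1] * u)), 1)
  # sign convention: largest-magnitude feature salience is positive
  expect_gt(lv1$v[which.max(abs(lv1$v[, 1])), 1], 0)

  # energy conservation and oracle equivalence on a random 4 x 50 matrix
  M <- matrix(rnorm(200), 4, 50)
  lv <- extractLvs(M)
  expect_equal(sum(lv$d^2), sum(M^2))
  oracle <- eigenSvdOracle(M)
  expect_equal(lv$d, oracle$d, tolerance = 1e-10)
  for (k in seq_along(lv$d)) {
    expect_equal(abs(sum(lv$u[, k] * oracle$u[, k])), 1, tolerance = 1e-8)
    expect_equal(abs(sum(lv$v[, k] * oracle$v[, k])), 1, tolerance = 1e-8)
  }
  expect_error(extractLvs(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("reconstruction identities hold for brain scores", {
  design <- studyDesign(c("g1", "g2"), c("c1", "c2"), 5)
  grids <- randomGrids(design, 2, 3, seed = 6)
  X <- buildMatrix(grids, design)
  M <- meanCenter(X)
  lv <- extractLvs(M)
  res <- taskPls(grids, design, nPerm = 0, nBoot = 0)
  lvs <- latentVariables(res)
  # scores of the mean-centered cell means reproduce u * s
  for (k in seq_along(lvs)) {
    sc <- projectBrainScores(M, lvs[[k]])
    expect_equal(unname(sc), unname(lv$u[, k] * lv$d[k]), tolerance = 1e-10)
  }
  # orthogonality of cell-mean score vectors across LVs
  s1 <- projectBrainScores(M, lvs[[1]])
  s2 <- projectBrainScores(M, lvs[[2]])
  expect_equal(sum(s1 * s2), 0, tolerance = 1e-10)
  expect_error(projectBrainScores(M[, 1:3], lvs[[1]]), "mismatch")
})

test_that("consistent relabeling permutes design saliences but not singular values", {
  design <- studyDesign(c("g1", "g2"), c("c1", "c2"), 4)
  grids <- randomGrids(design, 2, 3, seed = 7)
  res <- taskPls(grids, design, nPerm = 0, nBoot = 0)
  # swap group names (same data, relabeled)
  design2 <- studyDesign(c("g2", "g1"), c("c1", "c2"),
                         list(g2 = design@subjects$g2, g1 = design@subjects$g1))
  res2 <- taskPls(grids, design2, nPerm = 0, nBoot = 0)
  d1 <- vapply(latentVariables(res), function(l) l@singularValue, 0)
  d2 <- vapply(latentVariables(res2), function(l) l@singularValue, 0)
  expect_equal(d1, d2, tolerance = 1e-10)
  lv1 <- latentVariables(res)[[1]]@designSaliences
  lv2 <- latentVariables(res2)[[1]]@designSaliences
  expect_equal(lv2[names(lv1)], lv1, tolerance = 1e-8)
})

test_that("permutation p-values are deterministic, bounded, and add-one corrected", {
  design <- studyDesign(c("g1", "g2"), c("c1", "c2"), 6)
  # huge effect: cell means separated by 10 SD
  grids <- randomGrids(design, 2, 3, seed = 8,
                       shift = function(g, cn) if (g == "g1") 10 else -10)
  X <- buildMatrix(grids, design)
  p1 <- permutationTest(X, nPerm = 99, seed = 42)
  p2 <- permutationTest(X, nPerm = 99, seed = 42)
  expect_identical(p1$permP, p2$permP)
  expect_equal(p1$permP[1], 1 / 100)  # minimum attainable at nPerm = 99
  p3 <- permutationTest(X, nPerm = 99, seed = 43)
  expect_false(identical(p1$permP, p3$permP))
  expect_warning(permutationTest(X, nPerm = 5, seed = 1), "nPerm")
  # procrustes comparison mode also flags the huge effect
  pp <- permutationTest(X, nPerm = 99, seed = 42, mode = "procrustes")
  expect_equal(pp$permP[1], 1 / 100)
})

test_that("bootstrap ratios are deterministic and separate signal from noise", {
  design <- studyDesign(c("g1", "g2"), c("c1", "c2"), 8)
  # feature 1 carries a strong group effect; features 2-4 pure noise
  grids <- randomGrids(design, 1, 4, seed = 9,
                       shift = function(g, cn) {
                         m <- matrix(0, 1, 4)
                         m[1, 1] <- if (g == "g1") 3 else -3
                         m
                       })
  X <- buildMatrix(grids, design)
  b1 <- bootstrapSaliences(X, nBoot = 100, seed = 7)
  b2 <- bootstrapSaliences(X, nBoot = 100, seed = 7)
  expect_identical(b1$ratios, b2$ratios)
  expect_gt(abs(b1$ratios[1, 1]), 2)   # driver feature is stable
  expect_error(bootstrapSaliences(X, nBoot = 1, seed = 1), "nBoot")
  # sign alignment variant agrees on the dominant feature
  bs <- bootstrapSaliences(X, nBoot = 100, seed = 7, align = "sign")
  expect_gt(abs(bs$ratios[1, 1]), 2)
})

test_that("zero-salience features rarely exceed the bootstrap-ratio threshold", {
  # LV1 is anchored by a real effect on feature 1; features 2-5 carry
  # symmetric noise and should look unstable (|ratio| < 2) almost always
  nullHits <- 0; nullTot <- 0
  for (r in 1:12) {
    design <- studyDesign(c("g1", "g2"), "c1", 10)
    grids <- randomGrids(design, 1, 5, seed = 100 + r,
                         shift = function(g, cn) {
                           m <- matrix(0, 1, 5)
                           m[1, 1] <- if (g == "g1") 3 else -3
                           m
                         })
    X <- buildMatrix(grids, design)
    b <- bootstrapSaliences(X, nBoot = 60, seed = r)
    nullHits <- nullHits + sum(abs(b$ratios[2:5, 1]) >= 2)
    nullTot <- nullTot + 4
  }
  expect_lt(nullHits / nullTot, 0.10)
})

test_that("the engine is generic over MSE, SPD and ERP feature grids", {
  design <- studyDesign(c("g1", "g2"), c("pre", "post"), 4)
  mkGrids <- function(build) {
    grids <- list()
    set.seed(13)
    for (g in design@groups) for (cn in design@conditions)
      for (s in design@subjects[[g]]) grids[[paste(g, cn, s, sep = ".")]] <- build()
    grids
  }
  mseG <- mkGrids(function() {
    v <- matrix(abs(rnorm(3 * 10)), 3, 10)
    new("MseGrid", values = v, channelLabels = c("Fz", "Cz", "Pz"),
        featureValues = as.numeric(1:10), nEpochsAveraged = matrix(2L, 3, 10),
        params = mseParams())
  })
  spdG <- mkGrids(function() {
    v <- matrix(abs(rnorm(3 * 8)), 3, 8); v <- v / rowSums(v)
    new("SpdGrid", values = v, channelLabels = c("Fz", "Cz", "Pz"),
        featureValues = seq(0.4, 3.2, by = 0.4),
        nEpochsAveraged = matrix(2L, 3, 8))
  })
  erpG <- mkGrids(function() erpGrid(matrix(rnorm(3 * 12), 3, 12),
                                     times = seq(0, 440, by = 40),
                                     channels = c("Fz", "Cz", "Pz")))
  for (grids in list(mseG, spdG, erpG)) {
    res <- taskPls(grids, design, nPerm = 19, nBoot = 10, seed = 3)
    lvs <- latentVariables(res)
    # 4 cells, but grand-mean centering removes one dimension -> rank 3
    expect_equal(length(lvs), 3)
    expect_s4_class(lvs[[1]], "LatentVariable")
    expect_true(all(vapply(lvs, function(l) l@permP > 0 && l@permP <= 1, TRUE)))
    m <- salienceMap(res, 1, "featureSaliences")
    expect_equal(nrow(m), 3)
    # energy conservation after centering
    M <- meanCenter(res@X)
    expect_equal(sum(vapply(lvs, function(l) l@singularValue^2, 0)), sum(M^2))
  }
})
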