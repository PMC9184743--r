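# Independent oracles and small fixtures used across the suite.

# Brute-force sample entropy by exhaustive O(N^2) template enumeration,
# written against the definition only (Chebyshev distance, templates from
# the first N - m positions, pairs over i < j). Independent of the
# compiled implementation.
bruteSampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  D <- abs(outer(x, x, "-"))
  cheb <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) cheb <- pmax(cheb, D[(1:nt) + k, (1:nt) + k])
  cheb1 <- pmax(cheb, D[(1:nt) + m, (1:nt) + m])
  B <- sum(cheb[upper.tri(cheb)] <= r)
  A <- sum(cheb1[upper.tri(cheb1)] <= r)
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

# SVD via symmetric eigendecompositions (independent of svd()):
# d, u from eigen(M M'), v reconstructed as M'u / d.
eigenSvdOracle <- function(M) {
  e <- eigen(tcrossprod(M), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  keep <- d > max(dim(M)) * .Machine$double.eps * max(d)
  d <- d[keep]
  u <- e$vectors[, keep, drop = FALSE]
  v <- t(M) %*% u %*% diag(1 / d, length(d), length(d))
  list(d = d, u = u, v = v)
}

# population SD, mirroring the package's tolerance convention
popSdOracle <- function(x) sqrt(mean((x - mean(x))^2))

# small channel sets used to keep simulations fast
tinyChans <- c("Fz", "Cz")
fourChans <- c("Fz", "Cz", "Pz", "Oz")

# quiet per-subject MSE grid
quietMse <- function(rec, params = mseParams()) {
  suppressWarnings(mseGrid(rec, params))
}
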