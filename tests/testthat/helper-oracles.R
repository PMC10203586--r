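# Shared fixtures (built lazily, cached for the whole run) and the
# independent oracles used against the package's own implementations.

.fixtureCache <- new.env(parent = emptyenv())

cachedTrial <- function(profile = "tiny", seed = 1) {
  key <- paste(profile, seed, sep = "_")
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- simulateTrial(profile, seed = seed)
  .fixtureCache[[key]]
}

cachedStudy <- function(profile = "demo", seed = 11,
                        unit = "line_blues") {
  key <- paste("study", profile, seed, unit, sep = "_")
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- prepareStudy(cachedTrial(profile, seed),
                                         unit = unit)
  .fixtureCache[[key]]
}

# Columns with an exact target correlation structure, rescaled into [0, 2]
# so they can live in a MarkerMatrix. Base vectors are orthonormalized, so
# the empirical correlation matrix equals R exactly.
corColumns <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  M <- scale(matrix(rnorm(n * p), n), center = TRUE, scale = FALSE)
  B <- qr.Q(qr(M))               # orthonormal and exactly mean-zero
  Z <- B * sqrt(n - 1)           # unit sample variance
  X <- Z %*% chol(R)
  X * 0.2 + 1
}

# Brute-force minimizer of the elastic-net objective on a 2-predictor
# problem: coarse grid then local refinement.
bruteForceEnet2 <- function(X, y, l1, l2) {
  obj <- function(b1, b2)
    enetObjective(X, y, c(b1, b2), l1, l2)
  refine <- function(c1, c2, width, step) {
    g1 <- seq(c1 - width, c1 + width, by = step)
    g2 <- seq(c2 - width, c2 + width, by = step)
    vals <- outer(g1, g2, Vectorize(obj))
    ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    c(g1[ij[1]], g2[ij[2]])
  }
  b <- refine(0, 0, 2, 0.02)
  b <- refine(b[1], b[2], 0.03, 5e-4)
  refine(b[1], b[2], 7.5e-4, 1e-5)
}

# Independent PLS1 oracle: the scores of NIPALS PLS1 are the Gram-Schmidt
# orthogonalization of the Krylov sequence (XX')^h y on standardized data;
# this computes them without any deflation step.
plsKrylovScores <- function(X, y, k) {
  Xs <- scale(X)
  ys <- as.numeric(scale(y))
  K <- tcrossprod(Xs)
  V <- matrix(0, nrow(Xs), k)
  v <- K %*% ys
  for (h in seq_len(k)) {
    if (h > 1)
      for (j in seq_len(h - 1)) v <- v - V[, j] * sum(V[, j] * v)
    v <- v / sqrt(sum(v^2))
    V[, h] <- v
    v <- K %*% v
  }
  V
}

unitCols <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")

# max column-wise difference allowing sign flips
maxColDiffUpToSign <- function(A, B) {
  max(vapply(seq_len(ncol(A)), function(j)
    min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j]))),
    numeric(1)))
}

# Dense GLS oracle for line BLUEs on a toy design: direct V inverse.
glsBluesOracle <- function(plots, vc) {
  X <- outer(plots$line, sort(unique(plots$line)), "==") * 1
  colnames(X) <- sort(unique(plots$line))
  Zb <- outer(plots$block, unique(plots$block), "==") * 1
  Zs <- outer(plots$subBlock, unique(plots$subBlock), "==") * 1
  V <- vc$sigmaResid * diag(nrow(plots)) +
    vc$sigmaBlock * tcrossprod(Zb) + vc$sigmaSubBlock * tcrossprod(Zs)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% plots$yield)
  stats::setNames(as.numeric(beta), colnames(X))
}

# Balanced nested ANOVA method-of-moments estimators for
# y = mu + block + subblock(block) + e with b blocks, s sub-blocks per
# block, k plots per sub-block.
nestedAnovaOracle <- function(y, block, subBlock) {
  k <- length(y) / length(unique(subBlock))
  s <- length(unique(subBlock)) / length(unique(block))
  blockMeans <- tapply(y, block, mean)
  subMeans <- tapply(y, subBlock, mean)
  subOfBlock <- tapply(block, subBlock, function(b) b[1])
  msB <- s * k * sum((blockMeans - mean(y))^2) /
    (length(unique(block)) - 1)
  msS <- k * sum((subMeans - blockMeans[subOfBlock])^2) /
    (length(unique(subBlock)) - length(unique(block)))
  msE <- sum((y - subMeans[subBlock])^2) /
    (length(y) - length(unique(subBlock)))
  list(sigmaBlock = (msB - msS) / (s * k),
       sigmaSubBlock = (msS - msE) / k,
       sigmaResid = msE)
}

# A minimal random trial-like plot table (single environment) for
# mixed-model tests, with known variance components.
simNestedPlots <- function(nBlocks = 6, nSub = 4, k = 5, sigmaB = 0.3,
                           sigmaS = 0.15, sigmaE = 0.5, seed = 1) {
  set.seed(seed)
  block <- rep(sprintf("B%d", seq_len(nBlocks)), each = nSub * k)
  subBlock <- rep(sprintf("B%d_S%d", rep(seq_len(nBlocks), each = nSub),
                          rep(seq_len(nSub), nBlocks)), each = k)
  n <- length(block)
  y <- 10 + rnorm(nBlocks, 0, sqrt(sigmaB))[as.integer(factor(block))] +
    rnorm(nBlocks * nSub, 0, sqrt(sigmaS))[as.integer(factor(subBlock))] +
    rnorm(n, 0, sqrt(sigmaE))
  data.frame(plot = sprintf("P%03d", seq_len(n)), env = "E1",
             block = block, subBlock = subBlock, line = "L1",
             isCheck = FALSE, yield = y, stringsAsFactors = FALSE)
}

randomMarkerMatrix <- function(nLines, nMarkers, seed = 1,
                               prefix = "L") {
  set.seed(seed)
  p <- runif(nMarkers, 0.1, 0.9)
  d <- vapply(p, function(q) rbinom(nLines, 2, q), numeric(nLines))
  dimnames(d) <- list(sprintf("%s%04d", prefix, seq_len(nLines)),
                      sprintf("m%04d", seq_len(nMarkers)))
  markerMatrix(d)
}
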