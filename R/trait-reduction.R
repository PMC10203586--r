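#' @include AllClasses.R
NULL

#' Count non-redundant traits at a correlation threshold
#'
#' Greedy single pass in column order: a trait is retained only when its
#' maximum absolute correlation with all previously retained traits is
#' below the threshold -- the same rule used for marker pruning, applied to
#' the trait panel. Sweeping the threshold traces how a heavily redundant
#' panel (e.g. ~100 vegetation indices) collapses to its distinct traits.
#'
#' @param traitMatrix numeric matrix, observations x traits. Missing values
#'   are tolerated via pairwise-complete correlations.
#' @param threshold correlation threshold in (0, 1].
#' @return integer count of retained traits.
#' @export
uniqueTraitCount <- function(traitMatrix, threshold) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  X <- as.matrix(traitMatrix)
  p <- ncol(X)
  if (p <= 1) return(p)
  kept <- 1L
  for (j in 2:p) {
    r <- suppressWarnings(
      abs(stats::cor(X[, kept, drop = FALSE], X[, j],
                     use = "pairwise.complete.obs")))
    r[is.na(r)] <- 0
    if (max(r) < threshold) kept <- c(kept, j)
  }
  length(kept)
}

#' Cumulative explained variance of trait principal components
#'
#' Eigendecomposition of the trait correlation matrix (columns standardized
#' internally); returns the cumulative fraction of variance explained,
#' non-decreasing and ending at 1.
#'
#' @param traitMatrix numeric matrix, observations x traits (>= 2 traits).
#'   Rows with missing values are dropped.
#' @return numeric vector of cumulative explained-variance fractions.
#' @export
pcaCumvar <- function(traitMatrix) {
  X <- prepTraits(traitMatrix)
  if (ncol(X) < 2) stop("need at least two (non-constant) traits")
  ev <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cumsum(ev) / sum(ev)
}

# Shared cleanup: drop rows with any NA, then constant columns (warned).
prepTraits <- function(traitMatrix) {
  X <- as.matrix(traitMatrix)
  keepRow <- stats::complete.cases(X)
  if (!all(keepRow)) X <- X[keepRow, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant trait column(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
  }
  attr(X, "keptRows") <- which(keepRow)
  X
}

# Squared-loading mass per trait category and the > 25% dominance flags.
categoryShares <- function(loadings, categories) {
  if (is.null(categories)) {
    share <- matrix(1, 1, ncol(loadings),
                    dimnames = list("all", colnames(loadings)))
    return(list(share = share,
                dominant = rep(list("all"), ncol(loadings))))
  }
  sq <- loadings^2
  share <- apply(sq, 2, function(col) tapply(col, categories, sum) / sum(col))
  share <- as.matrix(share)
  dominant <- lapply(seq_len(ncol(share)),
                     function(j) rownames(share)[share[, j] > 0.25])
  list(share = share, dominant = dominant)
}

#' Principal component scores of the trait panel
#'
#' Standardized PCA of the traits; returns the first k component scores
#' with their correlations to yield attached for reporting.
#'
#' @param traitMatrix observations x traits matrix (rows with missing
#'   values dropped).
#' @param yield optional yield vector aligned with the rows of
#'   \code{traitMatrix}.
#' @param k number of components (default 3). Truncated with a warning when
#'   it exceeds the matrix rank.
#' @param categories optional per-trait category labels for the
#'   dominant-category report.
#' @return A [ComponentSet-class] of kind \code{"PCO"}.
#' @export
selectPCO <- function(traitMatrix, yield = NULL, k = 3, categories = NULL) {
  X <- prepTraits(traitMatrix)
  if (!is.null(categories)) categories <- categories[
    colnames(traitMatrix) %in% colnames(X)]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (k > rank) {
    warning("k exceeds rank; truncated to ", rank)
    k <- rank
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  yc <- rep(NA_real_, k)
  if (!is.null(yield)) {
    y <- yield[attr(X, "keptRows")]
    yc <- as.numeric(stats::cor(scores, y))
  }
  cs <- categoryShares(loadings, categories)
  new("ComponentSet", kind = "PCO", scores = scores, loadings = loadings,
      yieldCor = yc, categoryShare = cs$share, dominant = cs$dominant)
}

#' Partial least squares components with yield as the response
#'
#' NIPALS PLS1 on standardized traits: each component maximizes covariance
#' with the current yield residual, with predictor deflation between
#' components. The returned components are ordered by their contribution to
#' the fitted yield variance (the components that carry the largest share
#' of the regression fit come first), and each is tagged with the trait
#' categories dominating its loadings.
#'
#' @param traitMatrix observations x traits matrix (rows with missing
#'   values dropped).
#' @param yield numeric response vector aligned with the rows.
#' @param k number of components (>= 1).
#' @param categories optional per-trait category labels.
#' @return A [ComponentSet-class] of kind \code{"PLS"}; scores and loadings
#'   are in contribution order, with \code{attr(, "fitContribution")}
#'   holding each component's share of fitted-yield variance.
#' @export
plsComponents <- function(traitMatrix, yield, k, categories = NULL) {
  if (k < 1) stop("k must be >= 1")
  X0 <- prepTraits(traitMatrix)
  if (!is.null(categories)) categories <- categories[
    colnames(traitMatrix) %in% colnames(X0)]
  y0 <- yield[attr(X0, "keptRows")]
  if (length(y0) != nrow(X0)) stop("yield length must match trait rows")
  if (stats::sd(y0) == 0) stop("yield has zero variance")
  X <- scale(X0)
  y <- as.numeric(scale(y0))
  n <- length(y); p <- ncol(X)
  k <- min(k, p, n - 1)
  Tm <- matrix(0, n, k); Pm <- matrix(0, p, k); Wm <- matrix(0, p, k)
  q <- numeric(k)
  yr <- y
  for (h in seq_len(k)) {
    w <- crossprod(X, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { k <- h - 1L; break }
    w <- w / nw
    tt <- as.numeric(X %*% w)
    t2 <- sum(tt^2)
    Pm[, h] <- crossprod(X, tt) / t2
    q[h] <- sum(yr * tt) / t2
    X <- X - tcrossprod(tt, Pm[, h])
    yr <- yr - q[h] * tt
    Tm[, h] <- tt
    Wm[, h] <- w
  }
  if (k == 0) stop("no usable PLS component (traits orthogonal to yield?)")
  Tm <- Tm[, seq_len(k), drop = FALSE]
  Pm <- Pm[, seq_len(k), drop = FALSE]
  Wm <- Wm[, seq_len(k), drop = FALSE]
  q <- q[seq_len(k)]
  contrib <- q^2 * colSums(Tm^2) / n
  ord <- order(contrib, decreasing = TRUE)
  scores <- Tm[, ord, drop = FALSE]
  loadings <- Pm[, ord, drop = FALSE]
  colnames(scores) <- colnames(loadings) <- sprintf("PLS%d", seq_len(k))
  rownames(loadings) <- colnames(X0)
  yc <- as.numeric(stats::cor(scores, y0))
  cs <- categoryShares(loadings, categories)
  out <- new("ComponentSet", kind = "PLS", scores = scores,
             loadings = loadings, yieldCor = yc,
             categoryShare = cs$share, dominant = cs$dominant)
  attr(out, "fitContribution") <- contrib[ord] / sum(contrib)
  attr(out, "fitted") <- as.numeric(Tm %*% q) * stats::sd(y0) + mean(y0)
  attr(out, "projection") <- list(
    center = colMeans(X0), scale = apply(X0, 2, stats::sd),
    rotation = Wm %*% solve(crossprod(Pm, Wm)), order = ord)
  out
}

#' Project new observations onto fitted PLS components
#'
#' Applies the training-time standardization and the PLS rotation
#' (weights corrected for deflation) to new trait data, returning scores
#' in the same contribution order as the fitted component set.
#'
#' @param cs a PLS [ComponentSet-class] from [plsComponents()].
#' @param newTraits matrix with the training trait columns.
#' @return observations x components score matrix.
#' @export
componentScores <- function(cs, newTraits) {
  pj <- attr(cs, "projection")
  if (is.null(pj)) stop("component set carries no projection (PCO?)")
  X <- as.matrix(newTraits)[, names(pj$center), drop = FALSE]
  Xs <- sweep(sweep(X, 2, pj$center), 2, pj$scale, `/`)
  sc <- Xs %*% pj$rotation
  sc <- sc[, pj$order, drop = FALSE]
  colnames(sc) <- sprintf("PLS%d", seq_len(ncol(sc)))
  sc
}
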