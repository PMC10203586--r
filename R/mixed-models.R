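#' @include AllClasses.R
NULL

# Fixed-effect design for the block model: intercept + environment + line
# contrasts, skipping factors with a single level.
fixedDesign <- function(plots) {
  terms <- c("env", "line")[c(length(unique(plots$env)) > 1,
                              length(unique(plots$line)) > 1)]
  if (!length(terms)) return(matrix(1, nrow(plots), 1))
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(f, data.frame(lapply(plots[terms], factor)))
}

indicator <- function(fac) {
  fac <- factor(fac)
  Z <- matrix(0, length(fac), nlevels(fac),
              dimnames = list(NULL, levels(fac)))
  Z[cbind(seq_along(fac), as.integer(fac))] <- 1
  Z
}

#' EM-REML variance components for the block/sub-block model
#'
#' Fits yield = environment + line (fixed) + block (random) + sub-block
#' (random) + residual by EM-REML. Fixed effects are absorbed once so each
#' iteration reduces to small dense solves in the random-effect dimension.
#' Convergence when the successive change in REML log-likelihood falls
#' below \code{tol}; a warning (with the last iterate returned) is issued
#' otherwise.
#'
#' @param plots plot table with columns \code{yield}, \code{env},
#'   \code{line}, \code{block}, \code{subBlock}.
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter iteration cap (default 500).
#' @return list with \code{sigmaBlock}, \code{sigmaSubBlock},
#'   \code{sigmaResid} (variance estimates), \code{logLik} (REML, up to a
#'   constant), \code{logLikPath}, \code{iterations}, \code{converged}.
#' @export
remlBlocks <- function(plots, tol = 1e-8, maxIter = 500) {
  y <- plots$yield
  n <- length(y)
  if (length(unique(plots$block)) < 2)
    stop("variance components are not identifiable with a single block")
  linesPerBlock <- tapply(plots$line, plots$block,
                          function(l) length(unique(l)))
  if (length(unique(plots$line)) > 1 && all(linesPerBlock == 1))
    stop("design confounded: one line per block everywhere")
  X <- fixedDesign(plots)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  Zb <- indicator(plots$block)
  Zs <- indicator(plots$subBlock)
  Z <- cbind(Zb, Zs)
  qb <- ncol(Zb); qs <- ncol(Zs); q <- qb + qs
  ib <- seq_len(qb); is <- qb + seq_len(qs)

  XtX <- crossprod(X); XtXc <- chol(XtX)
  XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  Xty <- crossprod(X, y); Zty <- crossprod(Z, y)
  yty <- sum(y^2)
  solveX <- function(b) backsolve(XtXc, forwardsolve(t(XtXc), b))
  ZtZa <- ZtZ - crossprod(XtZ, solveX(XtZ))  # absorbed random-effect block
  Ztya <- Zty - crossprod(XtZ, solveX(Xty))

  vy <- stats::var(y)
  sb <- 0.1 * vy; ss <- 0.1 * vy; se <- 0.8 * vy
  floorV <- 1e-10 * vy
  ll0 <- -Inf; llPath <- numeric(0); converged <- FALSE
  restLogLik <- function(sb, ss, se) {
    dInv <- c(rep(se / sb, qb), rep(se / ss, qs))
    S <- ZtZ + diag(dInv, q)
    cS <- chol(S)
    SiZty <- backsolve(cS, forwardsolve(t(cS), Zty))
    SiZtX <- backsolve(cS, forwardsolve(t(cS), t(XtZ)))
    XVX <- (XtX - XtZ %*% SiZtX) / se
    XVy <- (Xty - XtZ %*% SiZty) / se
    yVy <- (yty - sum(Zty * SiZty)) / se
    cXV <- chol(XVX)
    yPy <- yVy - sum(forwardsolve(t(cXV), XVy)^2)
    lndetV <- n * log(se) + 2 * sum(log(diag(cS))) -
      (qb * log(se / sb) + qs * log(se / ss))
    -0.5 * (lndetV + 2 * sum(log(diag(cXV))) + yPy)
  }
  emStep <- function(th) {
    sb <- th[1]; ss <- th[2]; se <- th[3]
    dInv <- c(rep(se / sb, qb), rep(se / ss, qs))
    M <- ZtZa + diag(dInv, q)
    Minv <- chol2inv(chol(M))
    u <- as.numeric(Minv %*% Ztya)
    b <- solveX(Xty - XtZ %*% u)
    c(max(floorV, (sum(u[ib]^2) + se * sum(diag(Minv)[ib])) / qb),
      max(floorV, (sum(u[is]^2) + se * sum(diag(Minv)[is])) / qs),
      (yty - sum(b * Xty) - sum(u * Zty)) / (n - p))
  }
  th <- c(sb, ss, se)
  hist <- list()
  iter <- 0
  for (iter in seq_len(maxIter)) {
    th <- emStep(th)
    hist <- c(utils::tail(hist, 2), list(log(th)))
    # Aitken/Steffensen extrapolation on the log scale every few sweeps;
    # accepted only when it does not decrease the REML log-likelihood
    if (length(hist) == 3 && iter %% 4 == 0) {
      d1 <- hist[[2]] - hist[[1]]; d2 <- hist[[3]] - hist[[2]]
      r <- d2 / d1
      ok <- is.finite(r) & r > 0 & r < 1 & abs(d1) > 0
      acc <- hist[[3]]
      acc[ok] <- hist[[2]][ok] + d2[ok] / (1 - r[ok])
      thAcc <- pmax(exp(acc), floorV)
      if (restLogLik(thAcc[1], thAcc[2], thAcc[3]) >=
          restLogLik(th[1], th[2], th[3])) {
        th <- thAcc
        hist <- list()
      }
    }
    ll <- restLogLik(th[1], th[2], th[3])
    llPath <- c(llPath, ll)
    if (is.finite(ll0) && abs(ll - ll0) < tol) { converged <- TRUE; break }
    ll0 <- ll
  }
  sb <- th[1]; ss <- th[2]; se <- th[3]
  if (!converged)
    warning("EM-REML did not converge in ", maxIter,
            " iterations; returning last iterate")
  list(sigmaBlock = sb, sigmaSubBlock = ss, sigmaResid = se,
       logLik = llPath[length(llPath)], logLikPath = llPath,
       iterations = iter, converged = converged)
}

#' BLUEs of line yields per environment
#'
#' Generalized least squares line estimates given the random block /
#' sub-block structure: per environment, solves the GLS normal equations
#' with V = sigmaResid I + sigmaBlock Zb Zb' + sigmaSubBlock Zs Zs'. Lines
#' without plots in an environment get no row (no extrapolation).
#'
#' @param plots plot table (see [remlBlocks()]).
#' @param varcomp variance components from [remlBlocks()], or \code{NULL}
#'   to estimate them per environment.
#' @param excludeChecks drop check plots before estimation (default TRUE).
#' @return data.frame with columns \code{line}, \code{env}, \code{blue}
#'   (t/ha), \code{se}.
#' @export
computeBlues <- function(plots, varcomp = NULL, excludeChecks = TRUE) {
  if (excludeChecks && "isCheck" %in% names(plots))
    plots <- plots[!plots$isCheck, , drop = FALSE]
  out <- lapply(split(plots, plots$env), function(pe) {
    vc <- if (is.null(varcomp)) remlBlocks(pe) else varcomp
    X <- indicator(pe$line)
    Z <- cbind(indicator(pe$block), indicator(pe$subBlock))
    qb <- length(unique(pe$block)); qs <- length(unique(pe$subBlock))
    dInv <- c(rep(vc$sigmaResid / max(vc$sigmaBlock, 1e-12), qb),
              rep(vc$sigmaResid / max(vc$sigmaSubBlock, 1e-12), qs))
    S <- crossprod(Z) + diag(dInv, qb + qs)
    SiZtX <- solve(S, crossprod(Z, X))
    SiZty <- solve(S, crossprod(Z, pe$yield))
    XVX <- (crossprod(X) - crossprod(X, Z) %*% SiZtX) / vc$sigmaResid
    XVy <- (crossprod(X, pe$yield) -
              crossprod(X, Z) %*% SiZty) / vc$sigmaResid
    cXV <- chol(XVX)
    beta <- backsolve(cXV, forwardsolve(t(cXV), XVy))
    seB <- sqrt(diag(chol2inv(cXV)))
    data.frame(line = colnames(X), env = pe$env[1],
               blue = as.numeric(beta), se = seB,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' VanRaden genomic relationship matrix
#'
#' G = Z Z' / (2 sum p (1 - p)) with Z the dosage matrix centered by twice
#' the allele frequencies (p estimated as mean dosage / 2). Monomorphic
#' markers carry no information and are excluded.
#'
#' @param x a [MarkerMatrix-class] with no missing dosages.
#' @return list with \code{G} (line x line relationship matrix) and
#'   \code{p} (centering allele frequencies).
#' @export
grmVanRaden <- function(x) {
  stopifnot(is(x, "MarkerMatrix"))
  d <- dosages(x)
  if (anyNA(d)) stop("impute missing dosages before building the GRM")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic; GRM undefined")
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  list(G = G, p = p)
}

# REML eigen contrasts: an explicit orthonormal basis of the mean's
# complement (so the fixed effect cannot leak into zero-eigenvalue
# directions of a rank-deficient kernel), then diagonalize the projected
# kernel; contrasts z_i ~ N(0, sigmaG xi_i + sigmaE) independently.
remlContrasts <- function(K, y) {
  n <- length(y)
  B <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  e <- eigen(crossprod(B, K %*% B), symmetric = TRUE)
  U <- B %*% e$vectors
  list(xi = pmax(e$values, 0), z = as.numeric(crossprod(U, y)))
}

# EM-REML for the single-kernel model y = mu + u + e, u ~ N(0, sigmaG K).
emRemlKernel <- function(K, y, tol = 1e-8, maxIter = 500) {
  rc <- remlContrasts(K, y)
  xi <- rc$xi; z <- rc$z; m <- length(z)
  sg <- se <- stats::var(y) / 2
  floorV <- 1e-12 * stats::var(y)
  loglik <- function(th) {
    v <- th[1] * xi + th[2]
    -0.5 * sum(log(v) + z^2 / v)
  }
  emStep <- function(th) {
    v <- th[1] * xi + th[2]
    c(mean(th[1]^2 * xi * z^2 / v^2 + th[1] * th[2] / v),
      mean(th[2]^2 * z^2 / v^2 + th[1] * th[2] * xi / v))
  }
  th <- c(sg, se)
  hist <- list()
  ll0 <- -Inf; converged <- FALSE
  iter <- 0
  for (iter in seq_len(maxIter)) {
    th <- pmax(emStep(th), floorV)
    hist <- c(utils::tail(hist, 2), list(log(th)))
    if (length(hist) == 3 && iter %% 4 == 0) {
      d1 <- hist[[2]] - hist[[1]]; d2 <- hist[[3]] - hist[[2]]
      r <- d2 / d1
      ok <- is.finite(r) & r > 0 & r < 1 & abs(d1) > 0
      acc <- hist[[3]]
      acc[ok] <- hist[[2]][ok] + d2[ok] / (1 - r[ok])
      thAcc <- pmax(exp(acc), floorV)
      if (loglik(thAcc) >= loglik(th)) { th <- thAcc; hist <- list() }
    }
    ll <- loglik(th)
    if (is.finite(ll0) && abs(ll - ll0) < tol) { converged <- TRUE; break }
    ll0 <- ll
  }
  sg <- th[1]; se <- th[2]
  if (!converged)
    warning("GBLUP EM-REML did not converge; returning last iterate")
  list(sigmaG = sg, sigmaE = se, logLik = ll0, iterations = iter,
       converged = converged)
}

#' Univariate GBLUP with missing-response prediction
#'
#' Solves the mixed model y = mu + u + e with u ~ N(0, sigmaG G) on the
#' observed responses and returns BLUPs mu + u for every line in the GRM,
#' including lines with no record. Variance components are estimated by
#' EM-REML on the observed subset (eigen-rotated, so each iteration is
#' O(n)) unless supplied.
#'
#' @param y named numeric response vector; \code{NA} marks masked lines.
#'   Names must appear in the GRM.
#' @param grm list from [grmVanRaden()] (or any list with a \code{G}
#'   matrix covering all lines).
#' @param varcomp \code{"estimate"} (default) or a list with \code{sigmaG}
#'   and \code{sigmaE}.
#' @return list with \code{pred} (named predictions mu + u for all GRM
#'   lines), \code{mu}, \code{sigmaG}, \code{sigmaE}, \code{varcomp}
#'   details.
#' @export
gblupFit <- function(y, grm, varcomp = "estimate") {
  G <- grm$G
  obs <- names(y)[!is.na(y)]
  if (!length(obs)) stop("need at least one observed response")
  if (!all(obs %in% rownames(G)))
    stop("GRM must cover all response lines")
  yo <- y[obs]
  Koo <- G[obs, obs, drop = FALSE]
  vc <- if (identical(varcomp, "estimate")) emRemlKernel(Koo, yo)
        else varcomp
  sg <- vc$sigmaG; se <- vc$sigmaE
  if (sg <= 0) {
    mu <- mean(yo)
    pred <- stats::setNames(rep(mu, nrow(G)), rownames(G))
    return(list(pred = pred, mu = mu, sigmaG = sg, sigmaE = se,
                varcomp = vc))
  }
  V <- sg * Koo + diag(se, length(obs))
  cV <- tryCatch(chol(V), error = function(e) {
    warning("singular mixed-model system; ridge jitter applied")
    chol(V + diag(1e-8, length(obs)))
  })
  Vi1 <- backsolve(cV, forwardsolve(t(cV), rep(1, length(obs))))
  Viy <- backsolve(cV, forwardsolve(t(cV), yo))
  mu <- sum(Vi1 * yo) / sum(Vi1)
  r <- backsolve(cV, forwardsolve(t(cV), yo - mu))
  u <- sg * (G[, obs, drop = FALSE] %*% r)
  pred <- stats::setNames(as.numeric(mu + u), rownames(G))
  list(pred = pred, mu = mu, sigmaG = sg, sigmaE = se, varcomp = vc)
}

# Multivariate EM (complete-case): y_i | traits ~ N(mu, xi_i Gt + Rt) after
# eigen-rotation of the kernel; returns genetic (Gt) and residual (Rt)
# trait covariance matrices.
emMvKernel <- function(K, Y, tol = 1e-6, maxIter = 200) {
  n <- nrow(Y); t <- ncol(Y)
  e <- eigen(K, symmetric = TRUE)
  U <- e$vectors; lam <- pmax(e$values, 0)
  Yt <- crossprod(U, Y)
  x <- as.numeric(crossprod(U, rep(1, n)))
  S <- stats::cov(Y)
  step <- function(Gt, Rt) {
    Vinv <- vector("list", n)
    A <- matrix(0, t, t); bvec <- numeric(t)
    for (i in seq_len(n)) {
      Vi <- chol2inv(chol(lam[i] * Gt + Rt + diag(1e-10, t)))
      Vinv[[i]] <- Vi
      A <- A + x[i]^2 * Vi
      bvec <- bvec + x[i] * (Vi %*% Yt[i, ])
    }
    mu <- solve(A, bvec)
    GtN <- matrix(0, t, t); RtN <- matrix(0, t, t); ll <- 0
    for (i in seq_len(n)) {
      r <- Yt[i, ] - x[i] * mu
      Vi <- Vinv[[i]]
      GVr <- Gt %*% Vi %*% r
      RVr <- Rt %*% Vi %*% r
      GtN <- GtN + lam[i] * tcrossprod(GVr) + Gt - lam[i] * Gt %*% Vi %*% Gt
      RtN <- RtN + tcrossprod(RVr) + Rt - Rt %*% Vi %*% Rt
      ll <- ll - 0.5 * (-as.numeric(determinant(Vi)$modulus) +
                          sum(r * (Vi %*% r)))
    }
    list(Gt = (GtN + t(GtN)) / (2 * n), Rt = (RtN + t(RtN)) / (2 * n),
         mu = mu, ll = ll)
  }
  loglikAt <- function(Gt, Rt) {
    A <- matrix(0, t, t); bvec <- numeric(t); Vis <- vector("list", n)
    for (i in seq_len(n)) {
      Vi <- chol2inv(chol(lam[i] * Gt + Rt + diag(1e-10, t)))
      Vis[[i]] <- Vi
      A <- A + x[i]^2 * Vi
      bvec <- bvec + x[i] * (Vi %*% Yt[i, ])
    }
    mu <- solve(A, bvec)
    ll <- 0
    for (i in seq_len(n)) {
      r <- Yt[i, ] - x[i] * mu
      ll <- ll - 0.5 * (-as.numeric(determinant(Vis[[i]])$modulus) +
                          sum(r * (Vis[[i]] %*% r)))
    }
    ll
  }
  psdify <- function(M) {
    M <- (M + t(M)) / 2
    e <- eigen(M, symmetric = TRUE)
    e$vectors %*% (pmax(e$values, 1e-10) * t(e$vectors))
  }
  Gt <- S / 2; Rt <- S / 2
  mu <- numeric(t)
  hist <- list()
  ll0 <- -Inf; converged <- FALSE
  iter <- 0
  for (iter in seq_len(maxIter)) {
    st <- step(Gt, Rt)
    Gt <- st$Gt; Rt <- st$Rt; mu <- st$mu; ll <- st$ll
    hist <- c(utils::tail(hist, 2), list(c(Gt, Rt)))
    # likelihood-guarded vector extrapolation every few sweeps
    if (length(hist) == 3 && iter %% 4 == 0) {
      d1 <- hist[[2]] - hist[[1]]; d2 <- hist[[3]] - hist[[2]]
      r <- d2 / d1
      ok <- is.finite(r) & r > 0 & r < 1 & abs(d1) > 1e-14
      acc <- hist[[3]]
      acc[ok] <- hist[[2]][ok] + d2[ok] / (1 - r[ok])
      GtA <- psdify(matrix(acc[seq_len(t * t)], t))
      RtA <- psdify(matrix(acc[t * t + seq_len(t * t)], t))
      llA <- tryCatch(loglikAt(GtA, RtA), error = function(e) -Inf)
      if (llA >= ll) { Gt <- GtA; Rt <- RtA; ll <- llA; hist <- list() }
    }
    if (is.finite(ll0) && abs(ll - ll0) < tol * (abs(ll0) + 1)) {
      converged <- TRUE; break
    }
    ll0 <- ll
  }
  if (!converged)
    warning("multivariate EM did not converge; returning last iterate")
  list(Gt = Gt, Rt = Rt, mu = as.numeric(mu), logLik = ll0,
       iterations = iter, converged = converged)
}

#' Multivariate GBLUP: predict masked yields from genomic kinship and
#' observed co-responses
#'
#' Multi-trait mixed model with genetic covariance Gt (x) G and residual
#' covariance Rt (x) I, restricted to observed cells. The yield column may
#' be masked on validation lines while co-response columns (e.g. PCO or PLS
#' scores of the trait panel) are observed on all lines; predictions for
#' masked lines then condition on both the kinship to training lines and
#' the line's own co-responses. Covariance matrices are estimated by EM on
#' the subset of lines with all responses observed and then held fixed.
#'
#' @param Y lines x responses matrix (rownames = line ids); column
#'   \code{yieldCol} is the prediction target and may contain \code{NA}.
#' @param grm list with the relationship matrix \code{G} covering all rows
#'   of \code{Y}.
#' @param covariance \code{"estimate"} or a list with \code{Gt} and
#'   \code{Rt} (t x t PSD matrices).
#' @param yieldCol index or name of the yield column (default 1).
#' @return list with \code{pred} (named yield predictions for all lines),
#'   \code{Gt}, \code{Rt}, \code{mu}, \code{fit} (EM details when
#'   estimated).
#' @export
mvGblupFit <- function(Y, grm, covariance = "estimate", yieldCol = 1) {
  Y <- as.matrix(Y)
  t <- ncol(Y)
  if (is.character(yieldCol)) yieldCol <- match(yieldCol, colnames(Y))
  lines <- rownames(Y)
  G <- grm$G[lines, lines]
  co <- setdiff(seq_len(t), yieldCol)
  if (any(is.na(Y[, co])))
    stop("co-response columns must be observed on all lines")
  fit <- NULL
  if (identical(covariance, "estimate")) {
    compl <- !is.na(Y[, yieldCol])
    if (sum(compl) < t + 2)
      stop("too few complete lines to estimate covariances")
    fit <- emMvKernel(G[compl, compl], Y[compl, , drop = FALSE])
    Gt <- fit$Gt; Rt <- fit$Rt
  } else {
    Gt <- covariance$Gt; Rt <- covariance$Rt
    ev <- eigen((Gt + t(Gt)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("supplied Gt must be positive semi-definite")
    ev <- eigen((Rt + t(Rt)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("supplied Rt must be positive semi-definite")
  }
  n <- nrow(Y)
  # cells in trait-major order: cell = (trait - 1) * n + line
  obsMask <- !is.na(as.numeric(Y))
  SigG <- kronecker(Gt, G)
  SigR <- kronecker(Rt, diag(n))
  Sig <- SigG + SigR
  obsIdx <- which(obsMask)
  traitOf <- rep(seq_len(t), each = n)
  # GLS means per trait over observed cells
  Xc <- indicator(traitOf[obsIdx])
  So <- Sig[obsIdx, obsIdx]
  cS <- tryCatch(chol(So), error = function(e) {
    warning("singular multivariate system; ridge jitter applied")
    chol(So + diag(1e-8, length(obsIdx)))
  })
  yObs <- as.numeric(Y)[obsIdx]
  SiX <- backsolve(cS, forwardsolve(t(cS), Xc))
  Siy <- backsolve(cS, forwardsolve(t(cS), yObs))
  mu <- solve(crossprod(Xc, SiX), crossprod(Xc, Siy))
  resid <- yObs - Xc %*% mu
  alpha <- backsolve(cS, forwardsolve(t(cS), resid))
  # target cells: yield column for all lines; genetic covariance plus
  # cross-trait residual covariance with the line's own observed cells
  tgt <- (yieldCol - 1) * n + seq_len(n)
  Ct <- SigG[tgt, obsIdx, drop = FALSE]
  SigRt <- SigR[tgt, obsIdx, drop = FALSE]
  crossRes <- SigRt
  crossRes[, which(traitOf[obsIdx] == yieldCol)] <- 0
  pred <- as.numeric(mu[yieldCol] + (Ct + crossRes) %*% alpha)
  names(pred) <- lines
  list(pred = pred, Gt = Gt, Rt = Rt,
       mu = stats::setNames(as.numeric(mu), colnames(Y)), fit = fit)
}
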