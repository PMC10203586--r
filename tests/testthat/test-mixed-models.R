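test_that("EM-REML matches nested-ANOVA estimators on a balanced design", {
  plots <- simNestedPlots(nBlocks = 8, nSub = 4, k = 5, sigmaB = 0.3,
                          sigmaS = 0.15, sigmaE = 0.5, seed = 2)
  vc <- remlBlocks(plots)
  mom <- nestedAnovaOracle(plots$yield, plots$block, plots$subBlock)
  # REML equals ANOVA method-of-moments for balanced nested layouts when
  # all estimates are interior
  expect_equal(vc$sigmaBlock, mom$sigmaBlock, tolerance = 1e-4)
  expect_equal(vc$sigmaSubBlock, mom$sigmaSubBlock, tolerance = 1e-4)
  expect_equal(vc$sigmaResid, mom$sigmaResid, tolerance = 1e-4)
  expect_true(vc$converged)
  # log-likelihood never decreases along the EM path
  expect_true(all(diff(vc$logLikPath) > -1e-7))
  expect_true(all(c(vc$sigmaBlock, vc$sigmaSubBlock, vc$sigmaResid) >= 0))
})

test_that("EM-REML recovers a zero block variance and flags bad designs", {
  ests <- vapply(1:5, function(s) {
    plots <- simNestedPlots(nBlocks = 6, nSub = 4, k = 5, sigmaB = 0,
                            sigmaS = 0.1, sigmaE = 0.5, seed = 10 + s)
    suppressWarnings(remlBlocks(plots)$sigmaBlock)
  }, numeric(1))
  expect_lt(mean(ests), 0.03)
  plots <- simNestedPlots(seed = 3)
  plots$block <- "B1"
  expect_error(remlBlocks(plots), "single block")
  # one line per block everywhere: line effects absorb blocks
  conf <- data.frame(env = "E1", line = rep(c("L1", "L2"), each = 4),
                     block = rep(c("B1", "B2"), each = 4),
                     subBlock = rep(c("S1", "S2", "S3", "S4"), each = 2),
                     yield = rnorm(8) + 10)
  expect_error(remlBlocks(conf), "confounded")
})

test_that("BLUEs reduce to line means without block variance and match a dense GLS oracle", {
  trial <- cachedTrial("tiny", 5)
  plots <- plotTable(trial)
  pe <- plots[plots$env == "Cam16" & !plots$isCheck, ]
  vc0 <- list(sigmaBlock = 0, sigmaSubBlock = 0, sigmaResid = 0.4)
  b0 <- computeBlues(pe, varcomp = vc0)
  mn <- tapply(pe$yield, pe$line, mean)
  expect_equal(b0$blue, as.numeric(mn[b0$line]), tolerance = 1e-6)
  # toy 8-plot design against the direct matrix-inverse oracle
  toy <- data.frame(
    plot = paste0("P", 1:8), env = "E1",
    block = rep(c("B1", "B2"), each = 4),
    subBlock = rep(c("S1", "S2", "S3", "S4"), each = 2),
    line = c("L1", "L2", "L3", "L4", "L1", "L2", "L3", "L4"),
    isCheck = FALSE, yield = c(9.8, 10.4, 11.0, 10.1, 10.3, 10.9,
                               11.4, 10.0), stringsAsFactors = FALSE)
  vc <- list(sigmaBlock = 0.2, sigmaSubBlock = 0.1, sigmaResid = 0.5)
  bl <- computeBlues(toy, varcomp = vc)
  oracle <- glsBluesOracle(toy, vc)
  expect_equal(stats::setNames(bl$blue, bl$line), oracle,
               tolerance = 1e-8)
  # lines absent from an environment yield no row
  two <- rbind(toy, within(toy, {env <- "E2"; line[line == "L4"] <- "L1"}))
  blTwo <- computeBlues(two, varcomp = vc)
  expect_false(any(blTwo$line == "L4" & blTwo$env == "E2"))
})

test_that("the VanRaden GRM matches hand computation and panel expectations", {
  d <- matrix(c(0, 2, 0, 2,
                2, 0, 0, 2,
                0, 2, 2, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("m", 1:4)))
  g <- grmVanRaden(markerMatrix(d))
  p <- colMeans(d) / 2
  Z <- sweep(d, 2, 2 * p)
  expect_equal(g$G, tcrossprod(Z) / (2 * sum(p * (1 - p))),
               tolerance = 1e-12)
  # identical inbred lines: off-diagonal equals the diagonal entry
  d2 <- rbind(d, A2 = d["A", ])
  g2 <- grmVanRaden(markerMatrix(d2))
  expect_equal(g2$G["A", "A2"], g2$G["A", "A"], tolerance = 1e-12)
  # monomorphic markers excluded; fully monomorphic errors
  d3 <- cbind(d, m5 = c(2, 2, 2))
  expect_equal(length(grmVanRaden(markerMatrix(d3))$p), 4L)
  expect_error(grmVanRaden(markerMatrix(matrix(2, 2, 2,
    dimnames = list(c("x", "y"), c("a", "b"))))), "monomorphic")
  # large unrelated panel: mean off-diagonal near zero
  big <- grmVanRaden(randomMarkerMatrix(120, 400, seed = 6))$G
  expect_lt(abs(mean(big[upper.tri(big)])), 0.02)
})

test_that("GBLUP solves the closed forms and is invariant to line order", {
  set.seed(8)
  G <- diag(12)
  dimnames(G) <- list(sprintf("l%02d", 1:12), sprintf("l%02d", 1:12))
  y <- stats::setNames(rnorm(12, 10), rownames(G))
  vc <- list(sigmaG = 0.6, sigmaE = 1.2)
  f <- gblupFit(y, list(G = G), varcomp = vc)
  lam <- vc$sigmaE / vc$sigmaG
  expect_equal(f$pred - mean(y), (y - mean(y)) / (1 + lam),
               tolerance = 1e-10)
  # total shrinkage: all predictions collapse to the observed mean
  f0 <- gblupFit(y, list(G = G), varcomp = list(sigmaG = 0, sigmaE = 1))
  expect_true(all(abs(f0$pred - mean(y)) < 1e-12))
  # ordering invariance
  mm <- randomMarkerMatrix(40, 80, seed = 9)
  grm <- grmVanRaden(mm)
  yv <- stats::setNames(rnorm(40, 10), rownames(dosages(mm)))
  yv[1:8] <- NA
  p1 <- gblupFit(yv, grm, varcomp = vc)$pred
  perm <- sample(40)
  grmP <- list(G = grm$G[perm, perm])
  p2 <- gblupFit(yv[perm], grmP, varcomp = vc)$pred
  expect_equal(p1[names(p2)], p2, tolerance = 1e-9)
})

test_that("GBLUP equals ridge regression on markers (RR-BLUP equivalence)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50; p <- 30; cc <- runif(1, 2, 10)
    M <- matrix(rnorm(n * p), n,
                dimnames = list(sprintf("l%02d", 1:n), NULL))
    G <- tcrossprod(M) / cc
    yv <- stats::setNames(rnorm(n, 10), rownames(M))
    yv[sample(n, 12)] <- NA
    sg <- runif(1, 0.3, 1.5); se <- runif(1, 0.3, 1.5)
    f <- gblupFit(yv, list(G = G), varcomp = list(sigmaG = sg, sigmaE = se))
    obs <- !is.na(yv)
    b <- solve(crossprod(M[obs, ]) + cc * (se / sg) * diag(p),
               crossprod(M[obs, ], yv[obs] - f$mu))
    ridgePred <- f$mu + as.numeric(M %*% b)
    expect_lt(max(abs(ridgePred - f$pred)), 1e-6)
  }
})

test_that("kernel EM-REML recovers the simulated heritability ratio", {
  mm <- randomMarkerMatrix(400, 200, seed = 12)
  grm <- grmVanRaden(mm)
  set.seed(13)
  g <- as.numeric(scale(dosages(mm) %*% rnorm(200))) * sqrt(0.4 / 0.6)
  y <- stats::setNames(10 + g + rnorm(400), rownames(dosages(mm)))
  f <- gblupFit(y, grm)
  expect_lt(abs(f$sigmaG / (f$sigmaG + f$sigmaE) - 0.4), 0.1)
  expect_true(f$varcomp$converged)
})

test_that("multivariate GBLUP reduces to univariate under diagonal covariances", {
  set.seed(14)
  n <- 40
  M <- matrix(rnorm(n * 60), n,
              dimnames = list(sprintf("l%02d", 1:n), NULL))
  G <- tcrossprod(M) / 60
  yv <- stats::setNames(rnorm(n, 10), rownames(M))
  yv[1:10] <- NA
  co <- cbind(c1 = rnorm(n), c2 = rnorm(n))
  rownames(co) <- rownames(M)
  uni <- gblupFit(yv, list(G = G),
                  varcomp = list(sigmaG = 0.7, sigmaE = 1.1))
  Gt <- diag(c(0.7, 0.4, 0.3)); Rt <- diag(c(1.1, 0.8, 0.5))
  mv <- mvGblupFit(cbind(yield = yv, co), list(G = G),
                   covariance = list(Gt = Gt, Rt = Rt), yieldCol = 1)
  expect_lt(max(abs(mv$pred - uni$pred)), 1e-6)
  # with no masked yields the fitted values also agree
  yFull <- stats::setNames(rnorm(n, 10), rownames(M))
  uniF <- gblupFit(yFull, list(G = G),
                   varcomp = list(sigmaG = 0.7, sigmaE = 1.1))
  mvF <- mvGblupFit(cbind(yield = yFull, co), list(G = G),
                    covariance = list(Gt = Gt, Rt = Rt), yieldCol = 1)
  expect_lt(max(abs(mvF$pred - uniF$pred)), 1e-6)
  # non-PSD covariance rejected
  bad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(mvGblupFit(cbind(yield = yv, co), list(G = G),
                          covariance = list(Gt = bad, Rt = Rt)),
               "positive semi-definite")
})

test_that("an informative co-response improves masked-yield prediction", {
  # co-response genetically identical to yield, observed everywhere:
  # conditioning on it must beat the univariate prediction
  set.seed(15)
  n <- 120
  mm <- randomMarkerMatrix(n, 150, seed = 16)
  grm <- grmVanRaden(mm)
  g <- as.numeric(scale(dosages(mm) %*% rnorm(150)))
  lines <- rownames(dosages(mm))
  y <- stats::setNames(10 + g + rnorm(n, 0, 0.5), lines)
  co <- stats::setNames(g + rnorm(n, 0, 0.3), lines)
  accU <- accM <- numeric(5)
  for (r in 1:5) {
    set.seed(20 + r)
    mask <- sample(n, 40)
    ym <- y; ym[mask] <- NA
    pu <- gblupFit(ym, grm)$pred
    pm <- mvGblupFit(cbind(yield = ym, co = co), grm)$pred
    accU[r] <- accuracyR2(pu[mask], y[mask])
    accM[r] <- accuracyR2(pm[mask], y[mask])
  }
  expect_gt(mean(accM), mean(accU))
})
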