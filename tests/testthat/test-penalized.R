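test_that("standardization is exact, reversible and per-location aware", {
  set.seed(1)
  X <- matrix(rnorm(60 * 4, 5, 2), 60); colnames(X) <- paste0("x", 1:4)
  y <- rnorm(60, 10, 1.5)
  std <- standardizeXY(X, y)
  expect_lt(max(abs(colMeans(std$X))), 1e-12)
  expect_equal(unname(apply(std$X, 2, sd)), rep(1, 4), tolerance = 1e-12)
  expect_equal(invertTransformY(std$transform, std$y), y,
               tolerance = 1e-12)
  # already standardized input: identity up to numerics
  std2 <- standardizeXY(std$X, std$y)
  expect_lt(max(abs(std2$X - std$X)), 1e-12)
  # per-location mode: each environment centered and scaled
  env <- rep(c("A", "B"), each = 30)
  y2 <- y + ifelse(env == "A", 0, 4)
  stdL <- standardizeXY(X, y2, env)
  for (e in c("A", "B")) {
    expect_lt(abs(mean(stdL$y[env == e])), 1e-12)
    expect_equal(sd(stdL$y[env == e]), 1, tolerance = 1e-12)
  }
  expect_equal(invertTransformY(stdL$transform, stdL$y, env), y2,
               tolerance = 1e-12)
  # zero-SD column dropped with a warning
  Xz <- cbind(X, z = rep(2, 60))
  expect_warning(stdZ <- standardizeXY(Xz, y), "zero-SD")
  expect_false("z" %in% colnames(stdZ$X))
})

test_that("coordinate descent hits the unpenalized and fully penalized limits", {
  set.seed(2)
  n <- 50; p <- 5
  X <- scale(matrix(rnorm(n * p), n)); colnames(X) <- paste0("x", 1:p)
  y <- as.numeric(scale(X %*% c(1, -1, 0.5, 0, 0) + rnorm(n)))
  bOls <- unname(coef(lm(y ~ X - 1)))
  fit <- elasticNetCD(X, y, 0, 0, tol = 1e-9)
  expect_equal(unname(fit$coef), bOls, tolerance = 1e-6)
  # lambda1 at or above max |X'y|/n zeroes every coefficient
  lMax <- max(abs(crossprod(X, y)) / n)
  expect_true(all(elasticNetCD(X, y, lMax * 1.0001, 0)$coef == 0))
  expect_error(elasticNetCD(X, y, -0.1, 0), "non-negative")
})

test_that("coordinate descent agrees with the closed-form ridge solver", {
  set.seed(3)
  for (rep in 1:3) {
    n <- 40; p <- 8
    X <- scale(matrix(rnorm(n * p), n)); colnames(X) <- paste0("x", 1:p)
    y <- as.numeric(scale(rnorm(n) + X %*% rnorm(p)))
    for (l2 in c(0.1, 1)) {
      bR <- ridgeClosedForm(X, y, l2)
      bC <- elasticNetCD(X, y, 0, l2, tol = 1e-9)$coef
      expect_lt(max(abs(bR - bC)), 1e-6)
    }
  }
  # single-observation identity design: b = y / 2 at lambda2 = 1
  expect_equal(unname(ridgeClosedForm(matrix(1, 1, 1), 0.8, 1)), 0.4)
})

test_that("coordinate descent matches a brute-force objective grid", {
  set.seed(4)
  n <- 30
  X <- scale(matrix(rnorm(n * 2), n)); colnames(X) <- c("a", "b")
  y <- as.numeric(scale(X %*% c(0.8, -0.4) + rnorm(n, 0, 0.5)))
  for (pen in list(c(0.1, 0.1), c(0.05, 0), c(0.2, 1))) {
    bCd <- elasticNetCD(X, y, pen[1], pen[2], tol = 1e-10)$coef
    bBf <- bruteForceEnet2(X, y, pen[1], pen[2])
    expect_lt(max(abs(bCd - bBf)), 1e-4)
  }
})

test_that("the penalized objective is non-increasing over sweeps and the path shrinks", {
  set.seed(5)
  n <- 40; p <- 10
  X <- scale(matrix(rnorm(n * p), n)); colnames(X) <- paste0("x", 1:p)
  y <- as.numeric(scale(X %*% rnorm(p) + rnorm(n)))
  objs <- vapply(1:8, function(k)
    suppressWarnings(elasticNetCD(X, y, 0.05, 0.1, maxIter = k))$objective,
    numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
  # L1 norm of the solution is non-increasing in lambda1 at fixed lambda2
  l1s <- seq(0.01, 0.3, length.out = 8)
  norms <- vapply(l1s, function(l)
    sum(abs(elasticNetCD(X, y, l, 0.1)$coef)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("fitPredictor selects lambda by cross-validation and predicts on the original scale", {
  set.seed(6)
  n <- 120; p <- 15
  X <- matrix(rnorm(n * p), n); colnames(X) <- paste0("x", 1:p)
  env <- rep(c("A", "B"), each = n / 2)
  y <- 8 + ifelse(env == "A", 0, 3) + as.numeric(X %*% c(rep(0.6, 3),
                                                         rep(0, p - 3))) +
    rnorm(n, 0, 0.5)
  fit <- fitPredictor(X, y, penaltySpec("elastic_net"), env = env,
                      seed = 3)
  expect_s4_class(fit, "PenalizedFit")
  expect_true(fit@meta$converged)
  pr <- predict(fit, X, env = env)
  # predictions land on the t/ha scale: per-location means restored
  expect_lt(abs(mean(pr[env == "A"]) - mean(y[env == "A"])), 0.3)
  expect_lt(abs(mean(pr[env == "B"]) - mean(y[env == "B"])), 0.3)
  expect_gt(accuracyR2(pr, y), 0.5)
  # pure-noise predictors: out-of-sample accuracy collapses
  yN <- rnorm(n)
  fitN <- fitPredictor(X[1:80, ], yN[1:80], penaltySpec("lasso"), seed = 4)
  prN <- predict(fitN, X[81:120, ])
  expect_lt(suppressWarnings(accuracyR2(prN, yN[81:120])), 0.15)
  # column mismatch errors name the offender
  expect_error(predict(fit, X[, 1:10]), "missing predictor")
  X2 <- cbind(X, extra = rnorm(n))
  expect_error(predict(fit, X2), "unexpected")
  expect_error(fitPredictor(X[1:8, ], y[1:8], penaltySpec("lasso")),
               "fewer than 10")
})

test_that("ridge spec bypasses the L1 path and matches the paper's lambda convention", {
  spec <- penaltySpec("ridge")
  expect_equal(spec$lambda2, 1)
  expect_equal(spec$lambda1, 0)
  expect_equal(penaltySpec("lasso")$lambda2, 0)
  expect_equal(penaltySpec("elastic_net")$lambda2, 0.1)
  set.seed(7)
  X <- matrix(rnorm(300), 60); colnames(X) <- paste0("x", 1:5)
  y <- rnorm(60) + X[, 1]
  fit <- fitPredictor(X, y, spec)
  std <- standardizeXY(X, y)
  expect_equal(fit@coef, ridgeClosedForm(std$X, std$y, 1),
               tolerance = 1e-10)
})
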