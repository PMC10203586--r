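#' @include AllClasses.R
#' @useDynLib phenogs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Penalty specification for the penalized solvers
#'
#' Fixes the quadratic penalty per method label: 0 for lasso, 0.1 for
#' elastic net, 1 for ridge. The L1 strength is chosen per fit (internal
#' cross-validation by default), since only the quadratic penalty is part
#' of the method definition.
#'
#' @param label \code{"lasso"}, \code{"elastic_net"} or \code{"ridge"}.
#' @param lambda2 optional override of the quadratic penalty weight.
#' @return list with \code{label}, \code{lambda2} and for ridge
#'   \code{lambda1 = 0}.
#' @export
penaltySpec <- function(label = c("lasso", "elastic_net", "ridge"),
                        lambda2 = NULL) {
  label <- match.arg(label)
  if (is.null(lambda2))
    lambda2 <- switch(label, lasso = 0, elastic_net = 0.1, ridge = 1)
  if (lambda2 < 0) stop("lambda2 must be non-negative")
  out <- list(label = label, lambda2 = lambda2)
  if (label == "ridge") out$lambda1 <- 0
  out
}

#' Standardize predictors and response for penalized fitting
#'
#' Columns are centered and scaled to unit SD using the supplied
#' (training) rows only; zero-SD columns are dropped with a warning. The
#' response is centered/scaled globally, and additionally per environment
#' when labels are given, with the inverse transform stored so predictions
#' return to the original (t/ha) scale per location.
#'
#' @param X numeric predictor matrix (no missing values).
#' @param y numeric response.
#' @param env optional per-row environment labels enabling the
#'   per-location response transform.
#' @return list with \code{X} (standardized), \code{y} (standardized),
#'   \code{transform} (all parameters needed to transform new data and
#'   invert predictions).
#' @export
standardizeXY <- function(X, y, env = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed here")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  drop <- scl == 0
  if (any(drop)) {
    warning(sum(drop), " zero-SD predictor column(s) dropped")
    X <- X[, !drop, drop = FALSE]
    ctr <- ctr[!drop]; scl <- scl[!drop]
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  tf <- list(xCenter = ctr, xScale = scl,
             dropped = names(drop)[drop],
             yCenter = mean(y), yScale = stats::sd(y), perEnv = NULL)
  if (tf$yScale == 0) stop("response has zero variance")
  if (!is.null(env)) {
    pe <- do.call(rbind, lapply(split(y, env), function(v)
      data.frame(center = mean(v), scale = stats::sd(v))))
    pe$env <- rownames(pe)
    if (any(pe$scale == 0)) stop("response constant within an environment")
    tf$perEnv <- pe
    ys <- (y - pe$center[match(env, pe$env)]) /
      pe$scale[match(env, pe$env)]
  } else {
    ys <- (y - tf$yCenter) / tf$yScale
  }
  list(X = Xs, y = as.numeric(ys), transform = tf)
}

# Apply the stored predictor transform to new data, verifying columns.
applyTransformX <- function(tf, X) {
  X <- as.matrix(X)
  want <- names(tf$xCenter)
  have <- colnames(X)
  missing <- setdiff(want, have)
  if (length(missing))
    stop("missing predictor columns: ", paste(missing, collapse = ", "))
  X <- X[, want, drop = FALSE]
  sweep(sweep(X, 2, tf$xCenter), 2, tf$xScale, `/`)
}

# Invert the response transform: per-environment scale when stored and the
# environment was seen in training, the global transform otherwise.
invertTransformY <- function(tf, yhat, env = NULL) {
  if (!is.null(tf$perEnv) && !is.null(env)) {
    idx <- match(env, tf$perEnv$env)
    ctr <- ifelse(is.na(idx), tf$yCenter, tf$perEnv$center[idx])
    scl <- ifelse(is.na(idx), tf$yScale, tf$perEnv$scale[idx])
    yhat * scl + ctr
  } else {
    yhat * tf$yScale + tf$yCenter
  }
}

#' Elastic-net coordinate descent on standardized inputs
#'
#' Minimizes (1/2n) ||y - X b||^2 + lambda1 ||b||_1 + (lambda2/2)
#' ||b||_2^2 by cyclic coordinate descent with soft-thresholding; the 1/n
#' scaling keeps lambda values comparable across sample sizes.
#'
#' @param X standardized predictor matrix.
#' @param y centered response.
#' @param lambda1 L1 penalty weight (>= 0).
#' @param lambda2 quadratic penalty weight (>= 0).
#' @param tol convergence tolerance on the largest coefficient change per
#'   sweep (default 1e-7).
#' @param maxIter sweep cap (default 10000); non-convergence warns and is
#'   flagged in the result.
#' @param binit optional warm-start coefficients.
#' @return list with \code{coef} (named), \code{iterations},
#'   \code{converged}, \code{objective}.
#' @export
elasticNetCD <- function(X, y, lambda1, lambda2, tol = 1e-7,
                         maxIter = 10000, binit = NULL) {
  X <- as.matrix(X)
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be non-negative")
  if (is.null(binit)) binit <- numeric(ncol(X))
  res <- enet_cd_cpp(X, as.numeric(y), lambda1, lambda2,
                     as.numeric(binit), tol, as.integer(maxIter))
  if (!res$converged)
    warning("coordinate descent did not converge in ", maxIter, " sweeps")
  b <- stats::setNames(as.numeric(res$coef), colnames(X))
  list(coef = b, iterations = res$iterations, converged = res$converged,
       objective = enetObjective(X, y, b, lambda1, lambda2))
}

#' Elastic-net objective value
#'
#' @param X,y standardized data.
#' @param b coefficient vector.
#' @param lambda1,lambda2 penalty weights.
#' @return the penalized objective (1/2n) RSS + lambda1 |b|_1 +
#'   (lambda2/2) |b|_2^2.
#' @export
enetObjective <- function(X, y, b, lambda1, lambda2) {
  r <- y - as.numeric(as.matrix(X) %*% b)
  sum(r^2) / (2 * length(y)) + lambda1 * sum(abs(b)) +
    lambda2 / 2 * sum(b^2)
}

#' Closed-form ridge regression on standardized inputs
#'
#' b = (X'X/n + lambda2 I)^-1 X'y / n; the exact minimizer of the
#' coordinate-descent objective at lambda1 = 0, used as the ridge fast
#' path and as a solver cross-check.
#'
#' @param X standardized predictor matrix.
#' @param y centered response.
#' @param lambda2 quadratic penalty weight.
#' @return named coefficient vector.
#' @export
ridgeClosedForm <- function(X, y, lambda2) {
  X <- as.matrix(X)
  n <- nrow(X)
  A <- crossprod(X) / n + diag(lambda2, ncol(X))
  b <- tryCatch(solve(A, crossprod(X, y) / n), error = function(e) {
    warning("singular ridge system; jitter applied")
    solve(A + diag(1e-10, ncol(X)), crossprod(X, y) / n)
  })
  stats::setNames(as.numeric(b), colnames(X))
}

#' Fit a penalized yield model with internal lambda1 selection
#'
#' Standardizes the predictors (training rows only), optionally applies a
#' per-location response transform, and fits the penalized model. The L1
#' strength is chosen by 5-fold cross-validation over a 50-point
#' logarithmic path (largest lambda zeroing all coefficients down to
#' 1/1000 of it), minimizing validation MSE with warm starts; pass a
#' number for a fixed lambda1 instead.
#'
#' @param X predictor matrix (traits, markers, or their column-wise
#'   combination), with column names.
#' @param y response vector (original scale).
#' @param spec penalty specification from [penaltySpec()].
#' @param lambda1 \code{"cv"} (default) or a fixed non-negative value.
#' @param env optional per-row environment labels: enables the
#'   per-location response transform.
#' @param predictorSet tag stored in the fit (\code{"traits"},
#'   \code{"markers"}, \code{"combined"}).
#' @param nFolds,nLambda cross-validation settings.
#' @param seed seed for the fold assignment.
#' @return A [PenalizedFit-class].
#' @export
fitPredictor <- function(X, y, spec = penaltySpec("elastic_net"),
                         lambda1 = "cv", env = NULL,
                         predictorSet = "traits", nFolds = 5,
                         nLambda = 50, seed = 1) {
  if (length(y) < 10) stop("fewer than 10 training rows")
  std <- standardizeXY(X, y, env)
  Xs <- std$X; ys <- std$y
  n <- nrow(Xs)
  cvInfo <- NULL
  if (identical(spec$label, "ridge")) {
    l1 <- 0
    b <- ridgeClosedForm(Xs, ys, spec$lambda2)
    fit <- list(coef = b, iterations = 1L, converged = TRUE)
  } else {
    if (identical(lambda1, "cv")) {
      lMax <- max(abs(crossprod(Xs, ys)) / n)
      path <- exp(seq(log(lMax), log(lMax * 1e-2), length.out = nLambda))
      set.seed(childSeed(seed, "cvfolds"))
      fold <- sample(rep_len(seq_len(nFolds), n))
      mse <- matrix(NA_real_, nFolds, nLambda)
      for (f in seq_len(nFolds)) {
        tr <- fold != f
        bw <- numeric(ncol(Xs))
        for (k in seq_len(nLambda)) {
          # path fits only rank candidate penalties: a looser tolerance
          # than the final fit is ample for model selection
          r <- suppressWarnings(
            elasticNetCD(Xs[tr, , drop = FALSE], ys[tr], path[k],
                         spec$lambda2, tol = 1e-4, maxIter = 2000,
                         binit = bw))
          bw <- r$coef
          pred <- as.numeric(Xs[!tr, , drop = FALSE] %*% bw)
          mse[f, k] <- mean((ys[!tr] - pred)^2)
        }
      }
      cvMean <- colMeans(mse)
      l1 <- path[which.min(cvMean)]
      cvInfo <- list(path = path, cvMse = cvMean, lambda1 = l1)
    } else {
      l1 <- lambda1
    }
    fit <- elasticNetCD(Xs, ys, l1, spec$lambda2)
  }
  new("PenalizedFit",
      intercept = 0, coef = fit$coef, transform = std$transform,
      spec = list(lambda1 = l1, lambda2 = spec$lambda2,
                  label = spec$label),
      meta = list(iterations = fit$iterations,
                  converged = fit$converged,
                  predictorSet = predictorSet, cv = cvInfo))
}

#' Predict from a penalized fit on the original yield scale
#'
#' Applies the stored standardization to the new predictors, the linear
#' model, then the inverse response transform (per location when the fit
#' used one and environments are supplied; environments unseen in training
#' fall back to the global transform).
#'
#' @param object a [PenalizedFit-class].
#' @param newdata predictor matrix with the training columns.
#' @param env optional per-row environment labels.
#' @param ... ignored.
#' @return numeric predictions on the original response scale.
#' @export
setMethod("predict", "PenalizedFit", function(object, newdata, env = NULL,
                                              ...) {
  Xs <- applyTransformX(object@transform, newdata)
  extra <- setdiff(colnames(as.matrix(newdata)),
                   c(names(object@transform$xCenter),
                     object@transform$dropped))
  if (length(extra))
    stop("unexpected predictor columns: ", paste(extra, collapse = ", "))
  yhat <- object@intercept + as.numeric(Xs %*% object@coef)
  invertTransformY(object@transform, yhat, env)
})
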