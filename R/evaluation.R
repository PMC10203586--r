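#' @include AllClasses.R
NULL

#' Squared-correlation prediction accuracy
#'
#' The study's accuracy measure: squared Pearson correlation between
#' predicted and observed values. Defined as 0 (with a warning) when
#' either vector has zero variance.
#'
#' @param predicted,observed numeric vectors of equal length (>= 2).
#' @return accuracy in [0, 1].
#' @export
accuracyR2 <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ")
  if (length(predicted) < 2) stop("need at least two pairs")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("zero variance; accuracy defined as 0")
    return(0)
  }
  stats::cor(predicted, observed)^2
}

#' Spearman rank correlation of shared lines between two environments
#'
#' Restricts both BLUE vectors to the lines present in both (matched by
#' name), then computes the Spearman correlation with average ranks for
#' ties.
#'
#' @param bluesEnv1,bluesEnv2 named numeric vectors (names = line ids).
#' @return Spearman's rho.
#' @export
spearmanSharedLines <- function(bluesEnv1, bluesEnv2) {
  shared <- intersect(names(bluesEnv1), names(bluesEnv2))
  if (length(shared) < 2) stop("fewer than 2 shared lines")
  stats::cor(bluesEnv1[shared], bluesEnv2[shared], method = "spearman")
}

#' Draw train/test masks for one replicate of a scheme
#'
#' Fraction schemes: per environment, a seeded simple random sample
#' without replacement of the stated fraction of units forms the training
#' set; the remainder is the test set. Whole-location schemes: training
#' environments train, test environments test; supplement schemes
#' additionally move a random fraction of test-location units into
#' training. The replicate index perturbs the seed deterministically.
#'
#' @param scheme a [MaskingScheme-class].
#' @param units data.frame with columns \code{id} and \code{env}.
#' @param rep replicate index.
#' @param seed master seed.
#' @return list with \code{train} and \code{test} unit ids.
#' @export
makeMasks <- function(scheme, units, rep, seed = 1) {
  set.seed(childSeed(seed, paste0(scheme@name, "_rep", rep)))
  if (scheme@type == "fraction") {
    f <- scheme@fractions
    miss <- setdiff(names(f)[f > 0], unique(units$env))
    if (length(miss))
      stop("no units in environment(s): ", paste(miss, collapse = ", "))
    train <- character(0)
    for (e in names(f)) {
      ids <- units$id[units$env == e]
      nTr <- round(f[[e]] * length(ids))
      if (nTr > 0) train <- c(train, sample(ids, nTr))
    }
    inScheme <- units$id[units$env %in% names(f)]
    list(train = train, test = setdiff(inScheme, train))
  } else {
    train <- units$id[units$env %in% scheme@trainEnvs]
    test <- units$id[units$env %in% scheme@testEnvs]
    if (scheme@type == "supplement") {
      extra <- sample(test, round(scheme@supplementFraction * length(test)))
      train <- c(train, extra)
      test <- setdiff(test, extra)
    }
    list(train = train, test = test)
  }
}

#' Select trait columns by category and time point
#'
#' Returns the trial restricted to traits matching the requested
#' categories and/or time points (design columns and yield are untouched);
#' used for data-type and flight-date subset analyses.
#'
#' @param trial a [WheatTrial-class].
#' @param categories trait categories to keep (NULL = all).
#' @param timePoints time points to keep (NULL = all).
#' @return A [WheatTrial-class] with the filtered trait panel.
#' @export
subsetTraits <- function(trial, categories = NULL, timePoints = NULL) {
  panel <- traitPanel(trial)
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(categories)) {
    bad <- setdiff(categories, unique(panel$category))
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    keep <- keep & panel$category %in% categories
  }
  if (!is.null(timePoints)) {
    bad <- setdiff(timePoints, unique(panel$timePoint))
    if (length(bad)) stop("unknown time points: ", paste(bad, collapse = ", "))
    keep <- keep & panel$timePoint %in% timePoints
  }
  if (!any(keep)) stop("trait selection is empty")
  new("WheatTrial", plots = trial@plots,
      traits = trial@traits[, keep, drop = FALSE],
      panel = panel[keep, , drop = FALSE], envs = trial@envs,
      geno = trial@geno, truth = trial@truth)
}

#' Prepare a trial for the resampling engine
#'
#' Builds, once, everything the schemes reuse: marker QC and GRM, the unit
#' table (raw plots or line-by-environment BLUEs), the aligned trait
#' matrix (line means per environment in BLUE mode), and the per-unit
#' marker rows. Check plots are excluded from all prediction analyses.
#'
#' @param trial a [WheatTrial-class].
#' @param unit \code{"plots"} or \code{"line_blues"}.
#' @param runQC apply the full marker QC chain (default TRUE).
#' @return list consumed by [runScheme()]: \code{unit}, \code{units}
#'   (data.frame id/env/line), \code{y}, \code{traits}, \code{markers},
#'   \code{grm}, \code{panel}, \code{envs}, \code{qcReport}.
#' @export
prepareStudy <- function(trial, unit = c("plots", "line_blues"),
                         runQC = TRUE) {
  unit <- match.arg(unit)
  plots <- trial@plots[!trial@plots$isCheck, , drop = FALSE]
  traits <- trial@traits[!trial@plots$isCheck, , drop = FALSE]
  qc <- if (runQC) markerQC(genotypes(trial))
        else list(markers = imputeMean(genotypes(trial)), report = NULL)
  M <- dosages(qc$markers)
  grm <- grmVanRaden(qc$markers)
  if (unit == "plots") {
    units <- data.frame(id = plots$plot, env = plots$env,
                        line = plots$line, stringsAsFactors = FALSE)
    y <- stats::setNames(plots$yield, plots$plot)
    X <- traits
    rownames(X) <- plots$plot
  } else {
    blues <- computeBlues(plots)
    units <- data.frame(id = paste(blues$line, blues$env, sep = "@"),
                        env = blues$env, line = blues$line,
                        stringsAsFactors = FALSE)
    y <- stats::setNames(blues$blue, units$id)
    # line-mean traits per environment, aligned to the BLUE rows
    key <- paste(plots$line, plots$env, sep = "@")
    X <- apply(traits, 2, function(col)
      tapply(col, key, mean, na.rm = TRUE)[units$id])
    rownames(X) <- units$id
  }
  Mu <- M[units$line, , drop = FALSE]
  rownames(Mu) <- units$id
  list(unit = unit, units = units, y = y, traits = X, markers = Mu,
       grm = grm, panel = traitPanel(trial), envs = environments(trial),
       qcReport = qc$report)
}

# Predictor matrix for a penalized run; trait columns with missing values
# on the involved rows are dropped (year-restricted traits).
buildPredictors <- function(study, predictorSet, traitIds = NULL) {
  Xt <- study$traits
  if (!is.null(traitIds)) Xt <- Xt[, traitIds, drop = FALSE]
  Xm <- study$markers
  colnames(Xm) <- paste0("mk_", colnames(Xm))
  switch(predictorSet,
         traits = Xt,
         markers = Xm,
         combined = cbind(Xt, Xm))
}

resolveTraitSubset <- function(study, traitSubset) {
  if (is.null(traitSubset)) return(NULL)
  panel <- study$panel
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(traitSubset$categories))
    keep <- keep & panel$category %in% traitSubset$categories
  if (!is.null(traitSubset$timePoints))
    keep <- keep & panel$timePoint %in% traitSubset$timePoints
  if (!any(keep)) stop("trait selection is empty")
  panel$trait[keep]
}

#' Run one masking scheme for one method and predictor set
#'
#' For every replicate: build the masks, fit on the training units,
#' predict the test units and score the squared correlation per target
#' environment. Penalized methods (lasso, enet, ridge) work on raw plots
#' or line BLUEs with the per-location response transform; gblup and
#' mv_gblup work on line BLUEs, with the line-mean BLUE over the scheme's
#' environments as response (fraction schemes mask whole lines and report
#' environment \code{"pooled"}; whole-location schemes score each test
#' environment).
#'
#' @param study prepared data from [prepareStudy()].
#' @param method \code{"lasso"}, \code{"enet"}, \code{"ridge"},
#'   \code{"gblup"} or \code{"mv_gblup"}.
#' @param predictorSet \code{"traits"}, \code{"markers"} or
#'   \code{"combined"} (penalized methods only; genomic BLUP always uses
#'   markers).
#' @param scheme a [MaskingScheme-class].
#' @param traitSubset optional list with \code{categories} and/or
#'   \code{timePoints} restricting the trait predictors.
#' @param k number of co-response components (mv_gblup).
#' @param coKind co-response kind for mv_gblup: \code{"pco"} or
#'   \code{"pls"}.
#' @param lambda1 L1 selection rule passed to [fitPredictor()].
#' @param seed master seed; every replicate derives its own child seed.
#' @return data.frame of accuracy records: \code{scheme}, \code{method},
#'   \code{predictorSet}, \code{env}, \code{rep}, \code{accuracy},
#'   \code{nTest}.
#' @export
runScheme <- function(study, method = c("lasso", "enet", "ridge", "gblup",
                                        "mv_gblup"),
                      predictorSet = c("traits", "markers", "combined"),
                      scheme, traitSubset = NULL, k = 3,
                      coKind = c("pco", "pls"), lambda1 = "cv", seed = 1) {
  method <- match.arg(method)
  predictorSet <- match.arg(predictorSet)
  coKind <- match.arg(coKind)
  if (method %in% c("gblup", "mv_gblup")) {
    if (is.null(study$grm))
      stop("genomic BLUP requires genotypes in the prepared study")
    if (study$unit != "line_blues")
      stop("genomic BLUP schemes run on line BLUEs")
    predictorSet <- "markers"
  }
  if (!is.null(traitSubset) && is.null(study$panel))
    stop("trait subsets require the trait panel")
  traitIds <- resolveTraitSubset(study, traitSubset)
  records <- list()
  for (r in seq_len(scheme@nReps)) {
    recs <- if (method %in% c("lasso", "enet", "ridge")) {
      runPenalizedRep(study, method, predictorSet, scheme, traitIds,
                      lambda1, r, seed)
    } else {
      runGblupRep(study, method, scheme, traitIds, k, coKind, r, seed)
    }
    records[[r]] <- recs
  }
  out <- do.call(rbind, records)
  out$scheme <- scheme@name
  out$method <- method
  out$predictorSet <- predictorSet
  rownames(out) <- NULL
  out[, c("scheme", "method", "predictorSet", "env", "rep", "accuracy",
          "nTest")]
}

runPenalizedRep <- function(study, method, predictorSet, scheme, traitIds,
                            lambda1, rep, seed) {
  masks <- makeMasks(scheme, study$units, rep, seed)
  if (!length(masks$test)) stop(
    "scheme leaves no test units; use explicit held-out environments")
  X <- buildPredictors(study, predictorSet, traitIds)
  use <- rownames(X) %in% c(masks$train, masks$test)
  X <- X[use, , drop = FALSE]
  X <- X[, colSums(is.na(X)) == 0, drop = FALSE]
  tr <- rownames(X) %in% masks$train
  envOf <- study$units$env[match(rownames(X), study$units$id)]
  spec <- penaltySpec(switch(method, lasso = "lasso",
                             enet = "elastic_net", ridge = "ridge"))
  fit <- fitPredictor(X[tr, , drop = FALSE], study$y[rownames(X)[tr]],
                      spec = spec, lambda1 = lambda1, env = envOf[tr],
                      predictorSet = predictorSet,
                      seed = childSeed(seed, paste0("cv", rep)))
  te <- !tr
  pred <- predict(fit, X[te, , drop = FALSE], env = envOf[te])
  obs <- study$y[rownames(X)[te]]
  scorePerEnv(pred, obs, envOf[te], rep)
}

runGblupRep <- function(study, method, scheme, traitIds, k, coKind, rep,
                        seed) {
  G <- study$grm
  units <- study$units
  inScheme <- if (scheme@type == "fraction")
    units$env %in% names(scheme@fractions)
  else units$env %in% c(scheme@trainEnvs, scheme@testEnvs)
  units <- units[inScheme, , drop = FALSE]
  lines <- intersect(unique(units$line), rownames(G$G))
  if (scheme@type == "fraction") {
    # mask whole lines; response = line-mean BLUE over the scheme's envs
    f <- scheme@fractions[[1]]
    set.seed(childSeed(seed, paste0(scheme@name, "_rep", rep)))
    trainLines <- sample(lines, round(f * length(lines)))
    testLines <- setdiff(lines, trainLines)
    lineMean <- tapply(study$y[units$id], units$line, mean)[lines]
    yTrain <- lineMean
    yTrain[testLines] <- NA
    pred <- gblupPredict(study, method, yTrain, lines, traitIds, k, coKind,
                         units)
    data.frame(env = "pooled", rep = rep,
               accuracy = accuracyR2(pred[testLines],
                                     lineMean[testLines]),
               nTest = length(testLines), stringsAsFactors = FALSE)
  } else {
    trainUnits <- units[units$env %in% scheme@trainEnvs, , drop = FALSE]
    if (scheme@type == "supplement") {
      testIds <- units$id[units$env %in% scheme@testEnvs]
      set.seed(childSeed(seed, paste0(scheme@name, "_rep", rep)))
      extra <- sample(testIds,
                      round(scheme@supplementFraction * length(testIds)))
      trainUnits <- rbind(trainUnits, units[units$id %in% extra, ,
                                            drop = FALSE])
    }
    yTrain <- tapply(study$y[trainUnits$id], trainUnits$line, mean)
    yAll <- stats::setNames(rep(NA_real_, length(lines)), lines)
    yAll[names(yTrain)] <- yTrain
    pred <- gblupPredict(study, method, yAll, lines, traitIds, k, coKind,
                         units)
    out <- lapply(scheme@testEnvs, function(e) {
      idx <- units$env == e & !(units$id %in% trainUnits$id)
      obs <- study$y[units$id[idx]]
      ln <- units$line[idx]
      data.frame(env = e, rep = rep,
                 accuracy = accuracyR2(pred[ln], obs),
                 nTest = sum(idx), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
}

# Shared GBLUP prediction step: univariate on the masked response, or
# multivariate with PCO/PLS co-responses from line-mean traits.
gblupPredict <- function(study, method, yMasked, lines, traitIds, k,
                         coKind, units) {
  G <- list(G = study$grm$G[lines, lines])
  if (method == "gblup")
    return(gblupFit(yMasked, G)$pred)
  # line-mean traits over the scheme's units
  Xt <- study$traits[units$id, , drop = FALSE]
  if (!is.null(traitIds)) Xt <- Xt[, traitIds, drop = FALSE]
  Xl <- apply(Xt, 2, function(col) tapply(col, units$line, mean,
                                          na.rm = TRUE)[lines])
  Xl <- Xl[, colSums(is.na(Xl)) == 0, drop = FALSE]
  obsLines <- names(yMasked)[!is.na(yMasked)]
  if (coKind == "pco") {
    cs <- selectPCO(Xl, yield = NULL, k = k)
    scores <- cs@scores
  } else {
    cs <- plsComponents(Xl[obsLines, , drop = FALSE], yMasked[obsLines],
                        k = k)
    scores <- componentScores(cs, Xl)
  }
  Y <- cbind(yield = yMasked[lines], scores[lines, , drop = FALSE])
  mvGblupFit(Y, G, covariance = "estimate", yieldCol = 1)$pred
}

scorePerEnv <- function(pred, obs, env, rep) {
  out <- lapply(unique(env), function(e) {
    i <- env == e
    if (sum(i) < 2) return(NULL)
    data.frame(env = e, rep = rep,
               accuracy = suppressWarnings(accuracyR2(pred[i], obs[i])),
               nTest = sum(i), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate accuracy records
#'
#' Mean and SD of accuracy per (scheme, method, predictor set,
#' environment); when the environment table is supplied, pooled
#' within-year averages (locations equally weighted) are appended with
#' environment labels \code{"year:<year>"}.
#'
#' @param records accuracy records from [runScheme()] (row-bindable).
#' @param envs optional environment table (for the year pooling).
#' @return data.frame with columns \code{scheme}, \code{method},
#'   \code{predictorSet}, \code{env}, \code{mean}, \code{sd}, \code{n}.
#' @export
aggregateRecords <- function(records, envs = NULL) {
  grp <- interaction(records$scheme, records$method, records$predictorSet,
                     records$env, drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(records, grp), function(d)
    data.frame(scheme = d$scheme[1], method = d$method[1],
               predictorSet = d$predictorSet[1], env = d$env[1],
               mean = mean(d$accuracy), sd = stats::sd(d$accuracy),
               n = nrow(d), stringsAsFactors = FALSE)))
  agg$sd[is.na(agg$sd)] <- 0
  if (!is.null(envs)) {
    rec <- records[records$env %in% envs$env, , drop = FALSE]
    if (nrow(rec)) {
      rec$year <- envs$year[match(rec$env, envs$env)]
      # equal weighting: average per-env replicate means within year
      perEnv <- stats::aggregate(accuracy ~ scheme + method + predictorSet +
                                   env + year, rec, mean)
      pooled <- stats::aggregate(accuracy ~ scheme + method + predictorSet +
                                   year, perEnv, mean)
      agg <- rbind(agg, data.frame(
        scheme = pooled$scheme, method = pooled$method,
        predictorSet = pooled$predictorSet,
        env = paste0("year:", pooled$year), mean = pooled$accuracy,
        sd = NA_real_, n = NA_integer_, stringsAsFactors = FALSE))
    }
  }
  rownames(agg) <- NULL
  agg
}

#' One-tailed paired comparison of two accuracy record sets
#'
#' Reporting utility for method contrasts (e.g. multivariate vs univariate
#' GBLUP): a one-tailed t-test that \code{recordsA} has greater mean
#' accuracy than \code{recordsB}, paired by replicate when both cover the
#' same replicates.
#'
#' @param recordsA,recordsB accuracy record data.frames.
#' @return htest object from [stats::t.test()].
#' @export
compareAccuracy <- function(recordsA, recordsB) {
  paired <- identical(recordsA$rep, recordsB$rep) &&
    identical(recordsA$env, recordsB$env)
  stats::t.test(recordsA$accuracy, recordsB$accuracy,
                alternative = "greater", paired = paired)
}
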