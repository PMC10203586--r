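test_that("squared-correlation accuracy covers sign, ties and degeneracy", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  expect_equal(accuracyR2(x, x), 1)
  expect_equal(accuracyR2(-x, x), 1)
  y <- c(2.0, 3.1, 2.5, 4.8, 4.6)
  expect_equal(accuracyR2(x, y), cor(x, y)^2, tolerance = 1e-12)
  expect_warning(a0 <- accuracyR2(rep(1, 5), y), "zero variance")
  expect_equal(a0, 0)
  expect_error(accuracyR2(x, y[1:4]), "lengths differ")
  expect_error(accuracyR2(1, 2), "two pairs")
})

test_that("Spearman on shared lines uses average ranks and name matching", {
  b1 <- stats::setNames(c(1, 2, 3, 4, 5, 6), paste0("L", 1:6))
  b2 <- stats::setNames(c(6, 5, 4, 3, 2, 1), paste0("L", 1:6))
  expect_equal(spearmanSharedLines(b1, b1), 1)
  expect_equal(spearmanSharedLines(b1, b2), -1)
  # tie handled by average ranks: matches rank-then-Pearson
  b3 <- stats::setNames(c(2.0, 2.0, 3.5, 1.0, 5.0, 4.0), paste0("L", 1:6))
  expect_equal(spearmanSharedLines(b1, b3),
               cor(rank(b1), rank(b3)), tolerance = 1e-12)
  # only the intersection of lines is used
  b4 <- stats::setNames(c(5, 1, 2), c("L9", "L2", "L3"))
  expect_equal(spearmanSharedLines(b1, b4),
               cor(rank(b1[c("L2", "L3")]), rank(b4[c("L2", "L3")]),
                   method = "spearman"))
  expect_error(spearmanSharedLines(b1, b4["L9"]), "shared lines")
})

test_that("masks sample the stated fractions deterministically", {
  units <- data.frame(id = sprintf("u%03d", 1:150),
                      env = rep(c("A", "B"), c(100, 50)))
  sc <- maskingScheme("fraction", fractions = c(A = 0.25, B = 1),
                      nReps = 3)
  m1 <- makeMasks(sc, units, rep = 1, seed = 5)
  expect_equal(sum(units$env[match(m1$train, units$id)] == "A"), 25)
  expect_equal(sum(units$env[match(m1$train, units$id)] == "B"), 50)
  expect_equal(sum(units$env[match(m1$test, units$id)] == "A"), 75)
  expect_equal(sum(units$env[match(m1$test, units$id)] == "B"), 0)
  # identical seed and rep reproduce the masks; new rep perturbs them
  m1b <- makeMasks(sc, units, rep = 1, seed = 5)
  expect_identical(m1, m1b)
  m2 <- makeMasks(sc, units, rep = 2, seed = 5)
  expect_false(setequal(m1$train, m2$train))
  # all fractions zero rejected at construction
  expect_error(maskingScheme("fraction", fractions = c(A = 0, B = 0)),
               "positive")
  # whole-location masks split by environment; supplement moves a slice
  scW <- maskingScheme("whole_location", trainEnvs = "A", testEnvs = "B")
  mW <- makeMasks(scW, units, 1, 5)
  expect_setequal(mW$train, units$id[units$env == "A"])
  scS <- maskingScheme("supplement", trainEnvs = "A", testEnvs = "B",
                       supplementFraction = 0.2)
  mS <- makeMasks(scS, units, 1, 5)
  expect_equal(sum(units$env[match(mS$train, units$id)] == "B"), 10)
  expect_equal(length(mS$test), 40)
})

test_that("trait subsetting filters panel categories and flights", {
  trial <- cachedTrial("tiny", 1)
  sub <- subsetTraits(trial, categories = "multispectral",
                      timePoints = "F1")
  expect_true(all(traitPanel(sub)$category == "multispectral"))
  expect_true(all(traitPanel(sub)$timePoint == "F1"))
  expect_equal(colnames(traitValues(sub)), traitPanel(sub)$trait)
  # all categories: identity view
  all <- subsetTraits(trial, categories = unique(traitPanel(trial)$category))
  expect_identical(traitValues(all), traitValues(trial))
  expect_error(subsetTraits(trial, categories = "lidar"), "unknown")
  expect_error(subsetTraits(trial, categories = "soil",
                            timePoints = "F1"), "empty")
})

test_that("record aggregation reports means, SDs and pooled years", {
  rec <- data.frame(scheme = "s", method = "enet", predictorSet = "traits",
                    env = rep(c("Cam16", "Dux16"), each = 4),
                    rep = rep(1:4, 2),
                    accuracy = c(0.5, 0.6, 0.55, 0.45, 0.7, 0.7, 0.7, 0.7),
                    nTest = 50)
  envs <- data.frame(env = c("Cam16", "Dux16"), year = 2016L,
                     location = c("C", "D"), mean = c(11, 12))
  agg <- aggregateRecords(rec, envs)
  a1 <- agg[agg$env == "Cam16", ]
  expect_equal(a1$mean, mean(c(0.5, 0.6, 0.55, 0.45)))
  expect_equal(a1$sd, sd(c(0.5, 0.6, 0.55, 0.45)))
  expect_equal(agg[agg$env == "Dux16", "sd"], 0)
  # pooled year value: equal weighting of the two locations
  expect_equal(agg[agg$env == "year:2016", "mean"],
               (0.525 + 0.7) / 2, tolerance = 1e-12)
  one <- aggregateRecords(rec[1, , drop = FALSE])
  expect_equal(one$sd, 0)
})

test_that("the resampling engine produces reproducible per-environment records", {
  study <- cachedStudy("tiny", 1, unit = "plots")
  sc <- maskingScheme("fraction",
                      fractions = c(Cam16 = 0.5, Dux16 = 0.5),
                      nReps = 2)
  r1 <- runScheme(study, "enet", "traits", sc, seed = 9)
  r2 <- runScheme(study, "enet", "traits", sc, seed = 9)
  expect_identical(r1, r2)
  expect_setequal(unique(r1$env), c("Cam16", "Dux16"))
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1))
  expect_true(all(r1$nTest >= 2))
  r3 <- runScheme(study, "enet", "traits", sc, seed = 10)
  expect_false(identical(r1$accuracy, r3$accuracy))
  # trait subsets flow through: soil-only predictors lose the signal
  rSoil <- runScheme(study, "ridge", "traits", sc,
                     traitSubset = list(categories = "soil"), seed = 9)
  rSpec <- runScheme(study, "ridge", "traits", sc,
                     traitSubset = list(categories = c("multispectral",
                                                       "hyperspectral")),
                     seed = 9)
  expect_gt(mean(rSpec$accuracy), mean(rSoil$accuracy))
})

test_that("scheme and method compatibility is enforced", {
  study <- cachedStudy("tiny", 1, unit = "plots")
  sc <- maskingScheme("fraction", fractions = c(Cam16 = 1, Dux16 = 1),
                      nReps = 1)
  expect_error(runScheme(study, "enet", "traits", sc, seed = 1),
               "no test units")
  expect_error(runScheme(study, "gblup", scheme = sc, seed = 1),
               "line BLUEs")
  expect_error(maskingScheme("whole_location", trainEnvs = "A",
                             testEnvs = "A"), "disjoint")
})

test_that("genomic BLUP schemes run on line BLUEs and stay in range", {
  study <- cachedStudy("tiny", 1, unit = "line_blues")
  scF <- maskingScheme("fraction",
                       fractions = c(Cam16 = 0.8, Dux16 = 0.8),
                       unit = "line_blues", nReps = 2)
  rG <- runScheme(study, "gblup", scheme = scF, seed = 4)
  expect_equal(nrow(rG), 2L)
  expect_equal(unique(rG$env), "pooled")
  expect_true(all(rG$accuracy >= 0 & rG$accuracy <= 1))
  rMv <- runScheme(study, "mv_gblup", scheme = scF, k = 2,
                   coKind = "pco", seed = 4)
  expect_equal(nrow(rMv), 2L)
  rMvP <- runScheme(study, "mv_gblup", scheme = scF, k = 2,
                    coKind = "pls", seed = 4)
  expect_true(all(rMvP$accuracy >= 0 & rMvP$accuracy <= 1))
  scW <- maskingScheme("whole_location", trainEnvs = "Cam16",
                       testEnvs = "Dux16", unit = "line_blues",
                       nReps = 1)
  rW <- runScheme(study, "gblup", scheme = scW, seed = 4)
  expect_equal(rW$env, "Dux16")
})
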