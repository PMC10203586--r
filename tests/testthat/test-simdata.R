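test_that("Haldane map function covers zero, finite and asymptotic distances", {
  expect_identical(haldane(0), 0)
  expect_equal(haldane(50), (1 - exp(-1)) / 2, tolerance = 1e-12)
  expect_lt(abs(haldane(1e7) - 0.5), 1e-12)
  expect_error(haldane(-1), "non-negative")
})

test_that("founders are homozygous, frequency-symmetric and deterministic", {
  map <- geneticMap(2, 100, 25)
  f1 <- simulateFounders(27, map, seed = 42)
  f2 <- simulateFounders(27, map, seed = 42)
  expect_identical(dosages(f1), dosages(f2))
  expect_equal(nLines(f1), 27L)
  expect_true(all(dosages(f1) %in% c(0, 2)))
  # fixed frequency 0.5 with random minor-allele orientation: mean dosage
  # centers on 1
  fs <- simulateFounders(600, map, mafLow = 0.5, mafHigh = 0.5, seed = 7)
  expect_lt(abs(mean(dosages(fs)) - 1), 0.05)
  expect_error(simulateFounders(5, map, mafLow = 0.6, mafHigh = 0.7),
               "mafLow")
  expect_error(simulateFounders(1, map), "2 parents")
})

test_that("cross populations follow Mendelian expectations", {
  map <- geneticMap(2, 120, 15)
  f <- simulateFounders(4, map, seed = 2)
  d <- dosages(f)
  # identical parents: no segregation possible
  dId <- d; dId[2, ] <- dId[1, ]
  rownames(dId) <- rownames(d)
  off <- makeCross(markerMatrix(dId, map), rownames(d)[1:2], 8, seed = 3)
  expect_true(all(abs(sweep(dosages(off), 2, dId[1, ])) < 1e-12))
  # segregating markers: mean dosage over many lines ~ 1
  big <- makeCross(f, rownames(d)[1:2], 500, nPlants = 1, seed = 4)
  seg <- which(d[1, ] != d[2, ])
  expect_gt(length(seg), 3)
  mm <- colMeans(dosages(big)[, seg, drop = FALSE])
  se <- sqrt(0.5 / 500)  # conservative SE of a mean dosage in [0,2]
  expect_true(all(abs(mm - 1) < 5 * se))
  # single-plant F4 heterozygosity ~ 1/8 at segregating loci
  het <- mean(dosages(big)[, seg] == 1)
  expect_lt(abs(het - 0.125), 0.02)
  # three-way crosses accepted, wrong arity and het founders rejected
  tw <- makeCross(f, rownames(d)[1:3], 10, seed = 5)
  expect_equal(nLines(tw), 10L)
  expect_error(makeCross(f, rownames(d)[1], 5), "2 or 3 parents")
  dHet <- d; dHet[1, 1] <- 1
  expect_error(makeCross(markerMatrix(dHet, map), rownames(d)[1:2], 5),
               "homozygous")
})

test_that("bulk genotyping pools sibling plants by arithmetic mean", {
  expect_equal(unname(bulkGenotype(matrix(2, 6, 3))), rep(2, 3))
  pool <- matrix(c(0, 2, 2, 2, 0, 2), 6, 1)
  expect_equal(as.numeric(bulkGenotype(pool)), 4 / 3, tolerance = 1e-12)
  # large pools within a selfed family converge to dosage 1 at a
  # segregating locus (F4 genotype frequencies 3/8, 2/8, 3/8)
  set.seed(1)
  geno <- sample(c(0, 1, 2), 20000, replace = TRUE,
                 prob = c(3, 2, 3) / 8)
  expect_lt(abs(bulkGenotype(matrix(geno, ncol = 1)) - 1), 0.02)
  expect_error(bulkGenotype(matrix(numeric(0), 0, 2)), "at least one")
})

test_that("dry-matter adjustment matches the 85% reference formula", {
  expect_equal(adjustYield(7.3, 15), 7.3)
  expect_equal(adjustYield(10, 100), 0)
  expect_equal(adjustYield(10, 20), 10 * 80 / 85, tolerance = 1e-12)
  expect_error(adjustYield(10, 101), "moisture")
  expect_error(adjustYield(10, -2), "moisture")
})

test_that("yield simulation reproduces the configured GxE and heritability", {
  geno <- randomMarkerMatrix(1000, 150, seed = 5)
  envs <- data.frame(env = c("E1", "E2"), year = c(2016L, 2016L),
                     location = c("A", "B"), mean = c(10, 9))
  design <- data.frame(
    plot = sprintf("P%05d", 1:2000),
    env = rep(envs$env, each = 1000),
    block = rep(c("E1_B1", "E1_B2", "E2_B1", "E2_B2"), each = 500),
    subBlock = rep(sprintf("S%03d", 1:200), each = 10),
    line = rep(rownames(dosages(geno)), 2),
    isCheck = FALSE, stringsAsFactors = FALSE)
  sim <- simulateYield(geno, design, envs,
                       truthConfig(h2 = 0.4, rho = 0.3), seed = 8)
  g <- sim$truth$g
  expect_lt(abs(cor(g[, 1], g[, 2]) - 0.3), 0.05)
  # plot-level heritability: R^2 of yield on true genetic value
  for (e in envs$env) {
    pe <- sim$plots[sim$plots$env == e, ]
    gv <- g[pe$line, e]
    r2 <- summary(lm(pe$yield ~ gv))$r.squared
    expect_lt(abs(r2 - 0.4), 0.05)
  }
  # perfect correlation, no noise: identical rankings
  sim1 <- simulateYield(geno, design, envs,
                        truthConfig(h2 = 0.999, rho = 1,
                                    sigmaBlock = 1e-8,
                                    sigmaSubBlock = 1e-8,
                                    sigmaResid = 1e-6), seed = 9)
  g1 <- sim1$truth$g
  expect_equal(cor(g1[, 1], g1[, 2], method = "spearman"), 1)
  expect_error(
    simulateYield(geno, design, envs,
                  truthConfig(rho = matrix(c(1, 2, 2, 1), 2))),
    "positive semi-definite")
})

test_that("trait panel carries redundancy groups and category signal", {
  trial <- cachedTrial("demo", 11)
  panel <- traitPanel(trial)
  X <- traitValues(trial)
  plots <- plotTable(trial)
  # within a redundancy group traits are near-duplicates, per environment
  e1 <- plots$env == "Cam16"
  grp <- panel$group[match(colnames(X), panel$trait)]
  gTab <- table(grp)
  gBig <- as.integer(names(gTab)[gTab >= 2][1])
  cols <- which(grp == gBig)
  cc <- abs(cor(X[e1, cols]))
  expect_gt(min(cc[upper.tri(cc)]), 0.9)
  # soil traits carry no yield signal, spectral traits do
  soil <- panel$trait[panel$category == "soil"]
  hyper <- panel$trait[panel$category == "hyperspectral"]
  rSoil <- max(abs(cor(X[e1, soil, drop = FALSE], plots$yield[e1])))
  rHyper <- max(abs(cor(X[e1, hyper, drop = FALSE], plots$yield[e1])))
  expect_lt(rSoil, 0.15)
  expect_gt(rHyper, 0.4)
})

test_that("the replication layout yields the study's plot accounting", {
  spec <- replicationTable()
  expect_equal(sum(spec$nLines), 2992L)
  # every line: 4 plots across the four environments
  expect_true(all(rowSums(spec[, -1]) == 4))
  # every environment: one plot per line in total
  expect_true(all(colSums(spec[, -1] * spec$nLines) == 2992))
  # design builder honours it at a scaled size
  lines <- sprintf("L%03d", 1:299)
  spec2 <- scaleReplicationSpec(spec, 299)
  des <- buildDesign(lines, paste0("E", 1:4), spec2, seed = 3)
  expect_true(all(table(des$line) == 4))
  expect_true(all(table(des$env) == 299))
  # degenerate single environment, single replicate
  des1 <- buildDesign(lines, "E1",
                      data.frame(nLines = 299L, E1 = 1L), seed = 3)
  expect_equal(nrow(des1), 299L)
  expect_true(all(table(des1$line) == 1))
  expect_error(buildDesign(lines, "E1",
                           data.frame(nLines = 100L, E1 = 1L)),
               "sum")
})

test_that("trial simulation is deterministic and structurally valid", {
  t1 <- simulateTrial("tiny", seed = 21)
  t2 <- simulateTrial("tiny", seed = 21)
  expect_identical(dosages(genotypes(t1)), dosages(genotypes(t2)))
  expect_identical(plotTable(t1), plotTable(t2))
  expect_identical(traitValues(t1), traitValues(t2))
  t3 <- simulateTrial("tiny", seed = 22)
  expect_false(identical(plotTable(t1)$yield, plotTable(t3)$yield))
  # raw yields back out to the adjusted ones through the moisture formula
  p <- plotTable(t1)
  expect_equal(adjustYield(p$yieldRaw, p$moisture), p$yield,
               tolerance = 1e-10)
  expect_true(validObject(t1))
})
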