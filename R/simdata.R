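#' @include AllClasses.R
NULL

# Deterministic child-seed derivation: one master seed spawns independent,
# reproducible streams per component (founders, meiosis, design, noise...).
# Kept below 2^31 - 1 so it is always a valid R integer seed.
childSeed <- function(seed, key) {
  ints <- utf8ToInt(as.character(key))
  h <- sum(ints * seq_along(ints))
  v <- ((as.numeric(seed) %% 2147483647) * 48271 + h * 9973) %% 2147483647
  as.integer(v)
}

#' Haldane map function
#'
#' Converts a genetic distance into a recombination probability assuming
#' crossovers arrive as a Poisson process with no interference:
#' r = (1 - exp(-2d)) / 2 with d in Morgans.
#'
#' @param distanceCM genetic distance in centiMorgans (non-negative).
#' @return Recombination probability in [0, 0.5).
#' @examples
#' haldane(0)    # 0
#' haldane(50)   # ~0.316
#' @export
haldane <- function(distanceCM) {
  if (any(distanceCM < 0)) stop("genetic distance must be non-negative")
  (1 - exp(-2 * distanceCM / 100)) / 2
}

#' Build a uniform genetic map
#'
#' Wheat-like default: 21 chromosomes of 150 cM each with evenly spaced
#' markers. The map drives meiosis only; no analysis step uses positions.
#'
#' @param nChrom number of chromosomes.
#' @param chromLength chromosome length in cM (scalar or per-chromosome).
#' @param markersPerChrom markers per chromosome.
#' @return data.frame with columns \code{marker}, \code{chrom}, \code{pos}.
#' @export
geneticMap <- function(nChrom = 21, chromLength = 150, markersPerChrom = 10) {
  len <- rep_len(chromLength, nChrom)
  do.call(rbind, lapply(seq_len(nChrom), function(ch) {
    pos <- len[ch] * (seq_len(markersPerChrom) - 0.5) / markersPerChrom
    data.frame(marker = sprintf("C%02dM%03d", ch, seq_len(markersPerChrom)),
               chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
}

# Per-adjacent-marker recombination fractions for a whole map; chromosome
# boundaries get r = 0.5 (independent assortment), so a single cumulative
# pass simulates a full-genome gamete.
recombFractions <- function(map) {
  m <- nrow(map)
  if (m < 2) return(numeric(0))
  d <- diff(map$pos)
  r <- haldane(pmax(d, 0))
  r[diff(as.integer(factor(map$chrom, levels = unique(map$chrom)))) != 0] <- 0.5
  r
}

# One gamete from a diploid (h1, h2 haplotype vectors): random start
# haplotype, switch between haplotypes with the precomputed recombination
# fraction at each marker interval.
gameteFrom <- function(h1, h2, rf) {
  m <- length(h1)
  start <- stats::rbinom(1L, 1L, 0.5)
  if (m > 1) {
    sw <- stats::rbinom(m - 1L, 1L, rf)
    state <- (start + cumsum(c(0L, sw))) %% 2L
  } else state <- start
  ifelse(state == 0L, h1, h2)
}

#' Simulate founder genotypes
#'
#' Draws fully homozygous (inbred) founder lines. Each marker gets a minor
#' allele frequency uniform in [mafLow, mafHigh]; which allele is minor is
#' randomized per marker, so per-marker mean dosage is symmetric around 1.
#'
#' @param nParents number of founder lines (default 27, an elite parent pool
#'   typical of a commercial crossing programme).
#' @param map genetic map from [geneticMap()].
#' @param mafLow,mafHigh bounds of the per-marker minor allele frequency,
#'   0 < mafLow <= mafHigh <= 0.5.
#' @param seed integer seed.
#' @return A [MarkerMatrix-class] of homozygous dosages (0 or 2).
#' @export
simulateFounders <- function(nParents = 27, map = geneticMap(),
                             mafLow = 0.1, mafHigh = 0.5, seed = 1) {
  if (!(mafLow > 0 && mafLow <= mafHigh && mafHigh <= 0.5))
    stop("require 0 < mafLow <= mafHigh <= 0.5")
  if (nParents < 2) stop("need at least 2 parents")
  set.seed(childSeed(seed, "founders"))
  m <- nrow(map)
  maf <- stats::runif(m, mafLow, mafHigh)
  flip <- stats::rbinom(m, 1L, 0.5) == 1L
  p <- ifelse(flip, 1 - maf, maf)  # alt-allele frequency
  dos <- vapply(seq_len(m), function(j)
    2 * stats::rbinom(nParents, 1L, p[j]), numeric(nParents))
  dos <- matrix(dos, nrow = nParents,
                dimnames = list(sprintf("P%02d", seq_len(nParents)),
                                map$marker))
  new("MarkerMatrix", dosage = dos, map = map)
}

#' Pool sibling plants into one codominant line dosage
#'
#' Models DNA bulking: the line's dosage at each marker is the arithmetic
#' mean over the sampled sibling plants, giving fractional codominant scores.
#' An optional call-error rate replaces a plant's call with a uniform draw
#' from {0, 1, 2}, emulating relaxed array-calling thresholds.
#'
#' @param plantDosages plants x markers matrix of integer dosages.
#' @param callErrorRate per-call error probability (default 0).
#' @return numeric vector of pooled dosages in [0, 2].
#' @export
bulkGenotype <- function(plantDosages, callErrorRate = 0) {
  plantDosages <- rbind(plantDosages)
  if (nrow(plantDosages) < 1) stop("need at least one plant in the pool")
  if (callErrorRate > 0) {
    err <- matrix(stats::runif(length(plantDosages)) < callErrorRate,
                  nrow(plantDosages))
    if (any(err))
      plantDosages[err] <- sample(0:2, sum(err), replace = TRUE)
  }
  colMeans(plantDosages)
}

#' Simulate one cross population of bulk-genotyped inbred-derived lines
#'
#' For two parents: F1 = P1 x P2, each line is one F2 plant (meiosis under
#' the Haldane map, no interference) selfed for two generations; for three
#' parents: a (P1 x P2) F1 gamete is combined with a P3 gamete per line
#' before the two selfing generations. Each line's dosage is the bulk over
#' \code{nPlants} sibling F4 plants (each from its own selfed F3 plant).
#'
#' @param founders [MarkerMatrix-class] of homozygous parents.
#' @param parentIds 2 or 3 founder line ids.
#' @param nLines number of derived lines.
#' @param nPlants plants pooled per line (default 6).
#' @param callErrorRate per-call genotyping error rate passed to
#'   [bulkGenotype()].
#' @param seed integer seed.
#' @param prefix line id prefix.
#' @return A [MarkerMatrix-class] of fractional line dosages.
#' @export
makeCross <- function(founders, parentIds, nLines, nPlants = 6,
                      callErrorRate = 0, seed = 1, prefix = "X") {
  stopifnot(is(founders, "MarkerMatrix"))
  if (!length(parentIds) %in% c(2, 3))
    stop("a cross takes 2 or 3 parents")
  if (nLines < 1) stop("nLines must be >= 1")
  dos <- dosages(founders)[parentIds, , drop = FALSE]
  if (any(is.na(dos)) || !all(dos %in% c(0, 2)))
    stop("founders must be fully homozygous (dosages 0 or 2)")
  map <- markerMap(founders)
  rf <- recombFractions(map)
  set.seed(childSeed(seed, paste0("cross_", prefix)))
  haps <- dos / 2
  out <- matrix(NA_real_, nLines, ncol(dos),
                dimnames = list(sprintf("%s_%03d", prefix, seq_len(nLines)),
                                colnames(dos)))
  for (i in seq_len(nLines)) {
    if (length(parentIds) == 2) {
      f1 <- list(haps[1, ], haps[2, ])
    } else {
      # line-specific (P1 x P2) gamete united with a P3 gamete
      f1 <- list(gameteFrom(haps[1, ], haps[2, ], rf), haps[3, ])
    }
    f2 <- list(gameteFrom(f1[[1]], f1[[2]], rf),
               gameteFrom(f1[[1]], f1[[2]], rf))
    plants <- matrix(NA_real_, nPlants, ncol(dos))
    for (k in seq_len(nPlants)) {
      f3 <- list(gameteFrom(f2[[1]], f2[[2]], rf),
                 gameteFrom(f2[[1]], f2[[2]], rf))
      plants[k, ] <- gameteFrom(f3[[1]], f3[[2]], rf) +
                     gameteFrom(f3[[1]], f3[[2]], rf)
    }
    out[i, ] <- bulkGenotype(plants, callErrorRate)
  }
  new("MarkerMatrix", dosage = out, map = map)
}

#' The study's replication layout for 2,992 lines over four environments
#'
#' Six line classes with per-environment replicate counts; every line totals
#' four plots across the four environments and each environment carries one
#' plot per line in total (2,992 plots).
#'
#' @return data.frame with columns \code{nLines} and one replicate-count
#'   column per environment position (\code{E1}..\code{E4}).
#' @export
replicationTable <- function() {
  data.frame(nLines = c(367L, 381L, 381L, 367L, 748L, 748L),
             E1 = c(2L, 2L, 1L, 1L, 1L, 0L),
             E2 = c(1L, 1L, 2L, 2L, 1L, 0L),
             E3 = c(1L, 0L, 1L, 0L, 1L, 2L),
             E4 = c(0L, 1L, 0L, 1L, 1L, 2L))
}

#' Scale a replication layout to a different line total
#'
#' Class sizes are scaled proportionally and rounded; the largest class
#' absorbs the rounding remainder so sizes sum exactly to \code{nLines}.
#'
#' @param spec a replication data.frame as from [replicationTable()].
#' @param nLines target number of lines.
#' @return rescaled replication data.frame.
#' @export
scaleReplicationSpec <- function(spec, nLines) {
  sz <- spec$nLines / sum(spec$nLines) * nLines
  sz <- pmax(1L, round(sz))
  sz[which.max(sz)] <- sz[which.max(sz)] + (nLines - sum(sz))
  spec$nLines <- as.integer(sz)
  spec
}

#' Build a modified alpha-lattice trial design
#'
#' Assigns each line its per-environment replicate count from the
#' replication layout, then lays plots into two blocks per environment split
#' into small sub-blocks. Twice-replicated entries (and checks) appear in
#' both blocks; once-replicated entries are appended to the sub-blocks of a
#' randomly chosen block, mirroring a replicated alpha-lattice augmented
#' with un-replicated entries.
#'
#' @param lineIds character vector of test line ids.
#' @param envIds environment ids; must match the replicate-count columns of
#'   \code{replicationSpec} positionally.
#' @param replicationSpec data.frame: column \code{nLines} plus one
#'   replicate-count column per environment.
#' @param subBlockSize entries per sub-block (default 10).
#' @param checkIds ids of check varieties, replicated in both blocks of
#'   every environment and flagged \code{isCheck}.
#' @param seed integer seed for the randomization.
#' @return data.frame with columns \code{plot}, \code{env}, \code{block},
#'   \code{subBlock}, \code{line}, \code{isCheck}.
#' @export
buildDesign <- function(lineIds, envIds, replicationSpec, subBlockSize = 10,
                        checkIds = character(), seed = 1) {
  if (sum(replicationSpec$nLines) != length(lineIds))
    stop("replicationSpec line counts must sum to the number of lines")
  repCols <- setdiff(names(replicationSpec), "nLines")
  if (length(repCols) != length(envIds))
    stop("replicationSpec must have one replicate column per environment")
  set.seed(childSeed(seed, "design"))
  ord <- sample(lineIds)
  cls <- rep(seq_len(nrow(replicationSpec)), replicationSpec$nLines)
  out <- vector("list", length(envIds))
  for (e in seq_along(envIds)) {
    env <- envIds[e]
    reps <- replicationSpec[[repCols[e]]][cls]
    two <- ord[reps == 2]
    one <- ord[reps == 1]
    inB1 <- sample(c(rep(TRUE, ceiling(length(one) / 2)),
                     rep(FALSE, floor(length(one) / 2))))
    blocks <- list(c(two, checkIds, one[inB1]),
                   c(two, checkIds, one[!inB1]))
    rows <- do.call(rbind, lapply(1:2, function(b) {
      entries <- sample(blocks[[b]])
      if (!length(entries)) return(NULL)
      sb <- ceiling(seq_along(entries) / subBlockSize)
      data.frame(env = env,
                 block = sprintf("%s_B%d", env, b),
                 subBlock = sprintf("%s_B%d_S%03d", env, b, sb),
                 line = entries, stringsAsFactors = FALSE)
    }))
    rows$plot <- sprintf("%s_P%04d", env, seq_len(nrow(rows)))
    out[[e]] <- rows
  }
  des <- do.call(rbind, out)
  des$isCheck <- des$line %in% checkIds
  rownames(des) <- NULL
  des[, c("plot", "env", "block", "subBlock", "line", "isCheck")]
}

#' Dry-matter yield adjustment
#'
#' Standardizes raw combine yields to 85\% dry matter using the measured
#' grain moisture: adjusted = raw * (100 - moisture) / 85.
#'
#' @param rawYield raw plot yield (t/ha).
#' @param moisturePct grain moisture percentage in [0, 100].
#' @return adjusted yield at 85\% dry matter.
#' @export
adjustYield <- function(rawYield, moisturePct) {
  if (any(moisturePct < 0 | moisturePct > 100))
    stop("moisture must lie in [0, 100]")
  rawYield * (100 - moisturePct) / 85
}

#' Configuration of the yield-generating truth
#'
#' @param nQtl number of markers carrying the marker-determined (common)
#'   genetic component.
#' @param h2 plot-level heritability per environment (scalar recycled):
#'   var(g) / var(plot yield).
#' @param rho between-environment genetic correlation: a scalar for a
#'   compound-symmetric structure, or a full correlation matrix.
#' @param sigmaBlock,sigmaSubBlock,sigmaResid block, sub-block and residual
#'   variances, (t/ha)^2.
#' @return list of generating parameters for [simulateYield()].
#' @export
truthConfig <- function(nQtl = 100, h2 = 0.4, rho = 0.3,
                        sigmaBlock = 0.05, sigmaSubBlock = 0.05,
                        sigmaResid = 0.4) {
  list(nQtl = nQtl, h2 = h2, rho = rho, sigmaBlock = sigmaBlock,
       sigmaSubBlock = sigmaSubBlock, sigmaResid = sigmaResid)
}

# Expand rho into a validated correlation matrix over nEnv environments.
rhoMatrix <- function(rho, nEnv) {
  if (is.matrix(rho)) {
    P <- rho
  } else {
    P <- matrix(rho, nEnv, nEnv); diag(P) <- 1
  }
  if (!isSymmetric(unname(P)) || any(abs(diag(P) - 1) > 1e-10))
    stop("genetic correlation matrix must be symmetric with unit diagonal")
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("genetic correlation matrix must be positive semi-definite")
  P
}

#' Simulate multi-environment plot yields with GxE
#'
#' A marker-determined common genetic component u (effects on \code{nQtl}
#' markers, back-fitted so u has unit variance) is combined with
#' environment-specific deviations so that true genetic values across
#' environments have the configured correlation structure. For a scalar
#' (compound-symmetric) rho, g_e = sqrt(rho) u + sqrt(1 - rho) d_e with
#' independent deviations d_e, so every environment has the same
#' marker-determined share; a full matrix is honoured through its Cholesky
#' factor with u as the first factor. Plot yield (at 85\% dry matter) is
#' environment mean + genetic value + block + sub-block + residual; grain
#' moisture is drawn per plot and raw yield back-computed from it.
#'
#' @param geno [MarkerMatrix-class] of line dosages (the generating "true"
#'   genotypes; genotyping noise belongs to the marker matrix itself).
#' @param design design data.frame from [buildDesign()].
#' @param envs environment data.frame (\code{env}, \code{year},
#'   \code{location}, \code{mean}).
#' @param truth list from [truthConfig()].
#' @param seed integer seed.
#' @return list with \code{plots} (plot table incl. \code{yield},
#'   \code{yieldRaw}, \code{moisture}) and \code{truth} (ground-truth list:
#'   per-line common value \code{u}, lines x environments matrix \code{g},
#'   marker effects, variance components, block/sub-block effects,
#'   residuals).
#' @export
simulateYield <- function(geno, design, envs, truth = truthConfig(),
                          seed = 1) {
  set.seed(childSeed(seed, "yield"))
  dos <- dosages(geno)
  dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
  lines <- rownames(dos)
  nEnv <- nrow(envs)
  P <- rhoMatrix(truth$rho, nEnv)
  h2 <- rep_len(truth$h2, nEnv)

  qtl <- sample(ncol(dos), min(truth$nQtl, ncol(dos)))
  alpha <- stats::rnorm(length(qtl))
  u <- as.numeric(scale(dos[, qtl, drop = FALSE] %*% alpha))

  offDiag <- P[upper.tri(P)]
  if (nEnv > 1 && length(unique(round(offDiag, 12))) == 1) {
    rho <- offDiag[1]
    g <- sqrt(rho) * matrix(u, length(lines), nEnv) +
      sqrt(1 - rho) * matrix(stats::rnorm(length(lines) * nEnv),
                             length(lines), nEnv)
  } else {
    L <- t(chol(P + diag(1e-10, nEnv)))
    Fm <- cbind(u, matrix(stats::rnorm(length(lines) * (nEnv - 1)),
                          length(lines), nEnv - 1))
    g <- Fm %*% t(L)
  }
  colnames(g) <- envs$env
  rownames(g) <- lines

  noiseVar <- truth$sigmaBlock + truth$sigmaSubBlock + truth$sigmaResid
  sigmaG <- h2 * noiseVar / (1 - h2)
  g <- sweep(g, 2, sqrt(sigmaG), `*`)

  blocks <- unique(design$block)
  subBlocks <- unique(design$subBlock)
  bEff <- stats::setNames(stats::rnorm(length(blocks), 0,
                                       sqrt(truth$sigmaBlock)), blocks)
  sEff <- stats::setNames(stats::rnorm(length(subBlocks), 0,
                                       sqrt(truth$sigmaSubBlock)), subBlocks)
  resid <- stats::rnorm(nrow(design), 0, sqrt(truth$sigmaResid))

  envMean <- stats::setNames(envs$mean, envs$env)
  gPlot <- g[cbind(match(design$line, lines), match(design$env, envs$env))]
  yield <- pmax(0, envMean[design$env] + gPlot + bEff[design$block] +
                  sEff[design$subBlock] + resid)
  moisture <- pmin(35, pmax(8, stats::rnorm(nrow(design), 18, 1.5)))
  plots <- cbind(design,
                 data.frame(moisture = moisture,
                            yieldRaw = yield * 85 / (100 - moisture),
                            yield = yield))
  rownames(plots) <- NULL
  list(plots = plots,
       truth = list(u = stats::setNames(u, lines), g = g,
                    qtl = colnames(dos)[qtl],
                    alpha = stats::setNames(alpha, colnames(dos)[qtl]),
                    h2 = h2, rho = P, sigmaG = sigmaG,
                    sigmaBlock = truth$sigmaBlock,
                    sigmaSubBlock = truth$sigmaSubBlock,
                    sigmaResid = truth$sigmaResid,
                    blockEffects = bEff, subBlockEffects = sEff,
                    residuals = resid, envMeans = envMean))
}

#' Configuration of the plot-level trait panel generator
#'
#' Defaults emulate a season of high-throughput field phenotyping:
#' multispectral vegetation indices over five flights (signal peaking around
#' flowering), one post-flowering hyperspectral acquisition, ground-based
#' visual scores at three stages with near-zero yield signal, and two soil
#' conductivity covariates carrying none.
#'
#' @param nMulti,nHyper,nVisual,nSoil trait counts per category
#'   (multispectral split evenly over \code{flights}).
#' @param flights number of multispectral flight dates (F1..).
#' @param nGroups total number of redundancy groups; traits within a group
#'   share a latent so tightly that pruning at |r| > 0.9 collapses the panel
#'   to about \code{nGroups} distinct traits.
#' @param betaMulti per-flight correlation of the group latent with the
#'   plot-level crop-status signal (recycled over flights).
#' @param betaHyper,betaVisual,betaSoil the same for the other categories.
#' @param traitNoiseSD per-trait measurement noise SD on the latent scale;
#'   within-group correlation is 1 / (1 + traitNoiseSD^2).
#' @param envLoadingJitter SD of the per-environment multiplicative
#'   perturbation of group loadings: sensor calibration and crop-status
#'   differences make the trait-yield mapping location-specific, which is
#'   what gives whole-location transfer its cost.
#' @param envBiasSD SD of a per-(environment, trait) additive offset.
#' @param residualLoad weight of the plot residual inside the crop-status
#'   signal (traits see micro-environment, not only genetics).
#' @param nExtra2017 number of additional spectral traits only scored in the
#'   second year (emulates panels growing between seasons).
#' @return list of panel-generator parameters for [simulateTraits()].
#' @export
panelConfig <- function(nMulti = 50, nHyper = 40, nVisual = 12, nSoil = 2,
                        flights = 5, nGroups = 40,
                        betaMulti = c(0.30, 0.55, 0.75, 0.70, 0.40),
                        betaHyper = 0.75, betaVisual = 0.12, betaSoil = 0,
                        traitNoiseSD = 0.2, envLoadingJitter = 0.2,
                        envBiasSD = 0.25, residualLoad = 0.5,
                        nExtra2017 = 0) {
  if (traitNoiseSD < 0 || envBiasSD < 0)
    stop("noise SDs must be non-negative")
  list(nMulti = nMulti, nHyper = nHyper, nVisual = nVisual, nSoil = nSoil,
       flights = flights, nGroups = nGroups,
       betaMulti = rep_len(betaMulti, flights), betaHyper = betaHyper,
       betaVisual = betaVisual, betaSoil = betaSoil,
       traitNoiseSD = traitNoiseSD, envLoadingJitter = envLoadingJitter,
       envBiasSD = envBiasSD, residualLoad = residualLoad,
       nExtra2017 = nExtra2017)
}

# Panel skeleton: one row per trait with category, time point, base loading
# and redundancy group. Groups are allocated to (category, time) cells
# proportionally to cell size, at least one per cell.
panelSkeleton <- function(cfg) {
  perFlight <- diff(round(seq(0, cfg$nMulti, length.out = cfg$flights + 1)))
  cells <- data.frame(
    category = c(rep("multispectral", cfg$flights), "hyperspectral",
                 "visual", "visual", "visual", "soil"),
    timePoint = c(sprintf("F%d", seq_len(cfg$flights)), "POST",
                  "EARLY", "MID", "LATE", "SOIL"),
    n = c(perFlight, cfg$nHyper,
          diff(round(seq(0, cfg$nVisual, length.out = 4))), cfg$nSoil),
    beta = c(cfg$betaMulti, cfg$betaHyper, rep(cfg$betaVisual, 3),
             cfg$betaSoil),
    stringsAsFactors = FALSE)
  cells <- cells[cells$n > 0, ]
  nTot <- sum(cells$n)
  gAlloc <- pmax(1L, round(cells$n / nTot * cfg$nGroups))
  gAlloc <- pmin(gAlloc, cells$n)
  panel <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    grp <- sort(rep_len(seq_len(gAlloc[i]), cells$n[i]))
    data.frame(category = cells$category[i], timePoint = cells$timePoint[i],
               beta = cells$beta[i], cellGroup = grp,
               stringsAsFactors = FALSE)
  }))
  panel$group <- cumsum(!duplicated(
    paste(panel$category, panel$timePoint, panel$cellGroup)))
  panel$cellGroup <- NULL
  panel$trait <- sprintf("%s_%s_T%03d",
                         substr(panel$category, 1, 2), panel$timePoint,
                         seq_len(nrow(panel)))
  panel[, c("trait", "category", "timePoint", "group", "beta")]
}

#' Simulate a redundant plot-level trait panel
#'
#' Each plot carries a latent crop-status signal (its true genetic value
#' plus a share of its yield residual, standardized within environment).
#' Every redundancy group has one group latent correlated \code{beta} with
#' that signal (beta set per category and flight; spectral high, visual low,
#' soil zero) and independent noise otherwise; each trait is its group
#' latent (random sign) plus trait noise plus a per-environment offset.
#' Group loadings are jittered per environment, so the trait-to-yield
#' mapping differs slightly between locations.
#'
#' @param plots plot table from [simulateYield()].
#' @param truth ground-truth list from [simulateYield()].
#' @param envs environment data.frame.
#' @param cfg list from [panelConfig()].
#' @param seed integer seed.
#' @return list with \code{traits} (plots x traits matrix), \code{panel}
#'   (trait metadata: trait, category, timePoint, group, years) and
#'   \code{loadings} (environment x group loading matrix, ground truth).
#' @export
simulateTraits <- function(plots, truth, envs, cfg = panelConfig(),
                           seed = 1) {
  set.seed(childSeed(seed, "traits"))
  panel <- panelSkeleton(cfg)
  nG <- max(panel$group)
  nP <- nrow(plots)

  gPlot <- truth$g[cbind(match(plots$line, rownames(truth$g)),
                         match(plots$env, colnames(truth$g)))]
  sRaw <- gPlot + cfg$residualLoad * truth$residuals
  s <- stats::ave(sRaw, plots$env, FUN = function(v) as.numeric(scale(v)))

  beta0 <- vapply(seq_len(nG), function(g)
    panel$beta[match(g, panel$group)], numeric(1))
  envIds <- envs$env
  betaEnv <- outer(rep(1, length(envIds)), beta0) *
    (1 + matrix(stats::rnorm(length(envIds) * nG, 0, cfg$envLoadingJitter),
                length(envIds), nG))
  betaEnv <- pmin(pmax(betaEnv, -0.9), 0.9)
  rownames(betaEnv) <- envIds

  bMat <- betaEnv[match(plots$env, envIds), , drop = FALSE]
  eta <- matrix(stats::rnorm(nP * nG), nP, nG)
  latent <- bMat * s + sqrt(1 - bMat^2) * eta

  sgn <- sample(c(-1, 1), nrow(panel), replace = TRUE)
  bias <- matrix(stats::rnorm(length(envIds) * nrow(panel), 0,
                              cfg$envBiasSD),
                 length(envIds), nrow(panel), dimnames = list(envIds, NULL))
  X <- latent[, panel$group, drop = FALSE]
  X <- sweep(X, 2, sgn, `*`) +
    matrix(stats::rnorm(nP * nrow(panel), 0, cfg$traitNoiseSD), nP) +
    bias[match(plots$env, envIds), , drop = FALSE]
  colnames(X) <- panel$trait

  panel$years <- "both"
  if (cfg$nExtra2017 > 0) {
    spectral <- which(panel$category %in% c("multispectral", "hyperspectral"))
    lateOnly <- utils::tail(spectral, cfg$nExtra2017)
    panel$years[lateOnly] <- "year2"
    yr1 <- plots$env %in% envs$env[envs$year == min(envs$year)]
    X[yr1, lateOnly] <- NA
  }
  panel$beta <- NULL
  list(traits = X, panel = panel, loadings = betaEnv)
}

#' Simulate a complete multi-environment trial
#'
#' End-to-end generator: founders, cross populations (biparental and
#' three-way) with bulk-sampled noisy genotypes, environments, a modified
#' alpha-lattice design, GxE plot yields and the redundant trait panel --
#' bundled as a [WheatTrial-class].
#'
#' Three profiles are provided. \code{"tiny"} (4 crosses x 10 lines, 50
#' markers, 2 environments) is unit-test scale; \code{"demo"} (8 crosses x
#' 40 lines, 300 markers, 4 environments) runs a full study in minutes;
#' \code{"paper_shape"} reproduces the study dimensions (44 crosses -- 39
#' biparental, 5 three-way -- of 68 lines each from 27 parents, 2,992 lines,
#' 4 environments, ~104 traits).
#'
#' @param profile one of \code{"tiny"}, \code{"demo"}, \code{"paper_shape"}.
#' @param seed master integer seed; all component seeds derive from it.
#' @param config optional list overriding profile defaults; recognised
#'   entries: \code{nParents}, \code{nCrosses}, \code{nThreeWay},
#'   \code{linesPerCross}, \code{map} (data.frame), \code{envs}
#'   (data.frame), \code{replicationSpec}, \code{subBlockSize},
#'   \code{nChecks}, \code{nPlants}, \code{callErrorRate},
#'   \code{missingRate}, \code{truth} (see [truthConfig()]), \code{panel}
#'   (see [panelConfig()]).
#' @return A [WheatTrial-class] with simulation truth attached.
#' @export
simulateTrial <- function(profile = c("demo", "tiny", "paper_shape"),
                          seed = 1, config = list()) {
  profile <- match.arg(profile)
  base <- switch(profile,
    tiny = list(nParents = 8, nCrosses = 4, nThreeWay = 1,
                linesPerCross = 10,
                map = geneticMap(5, 150, 10),
                envs = defaultEnvs(2),
                panel = panelConfig(nMulti = 6, nHyper = 4, nVisual = 3,
                                    nSoil = 1, flights = 2, nGroups = 5)),
    demo = list(nParents = 16, nCrosses = 8, nThreeWay = 1,
                linesPerCross = 40,
                map = geneticMap(10, 150, 30),
                envs = defaultEnvs(4),
                panel = panelConfig(nMulti = 30, nHyper = 20, nVisual = 8,
                                    nSoil = 2, flights = 5, nGroups = 15)),
    paper_shape = list(nParents = 27, nCrosses = 44, nThreeWay = 5,
                       linesPerCross = 68,
                       map = geneticMap(21, 150, 20),
                       envs = defaultEnvs(4),
                       panel = panelConfig(nExtra2017 = 26)))
  base$nChecks <- 2
  base$subBlockSize <- 10
  base$nPlants <- 6
  base$callErrorRate <- 0.02
  base$missingRate <- 0.02
  base$truth <- truthConfig()
  cfg <- utils::modifyList(base, config)

  founders <- simulateFounders(cfg$nParents, cfg$map, seed = seed)
  plan <- crossPlan(cfg$nParents, cfg$nCrosses, cfg$nThreeWay, seed)
  crosses <- lapply(seq_len(cfg$nCrosses), function(i) {
    makeCross(founders, plan[[i]], cfg$linesPerCross,
              nPlants = cfg$nPlants, callErrorRate = cfg$callErrorRate,
              seed = childSeed(seed, paste0("meiosis", i)),
              prefix = sprintf("X%02d", i))
  })
  dos <- do.call(rbind, lapply(crosses, dosages))
  if (cfg$missingRate > 0) {
    set.seed(childSeed(seed, "missing"))
    dos[matrix(stats::runif(length(dos)) < cfg$missingRate,
               nrow(dos))] <- NA
  }
  geno <- new("MarkerMatrix", dosage = dos, map = cfg$map)

  envs <- cfg$envs
  if (is.null(cfg$replicationSpec)) {
    spec <- replicationTable()[, c("nLines", paste0("E", seq_len(nrow(envs))))]
    spec <- spec[rowSums(spec[, -1, drop = FALSE]) > 0, , drop = FALSE]
    cfg$replicationSpec <- scaleReplicationSpec(spec, nrow(dos))
  }
  checkIds <- if (cfg$nChecks > 0) sprintf("CHK%d", seq_len(cfg$nChecks))
              else character()
  design <- buildDesign(rownames(dos), envs$env, cfg$replicationSpec,
                        subBlockSize = cfg$subBlockSize,
                        checkIds = checkIds, seed = seed)

  # checks need genetic values too: give them founder-like genotypes
  if (length(checkIds)) {
    set.seed(childSeed(seed, "checks"))
    chk <- dosages(founders)[sample(cfg$nParents, length(checkIds)), ,
                             drop = FALSE]
    rownames(chk) <- checkIds
    genoAll <- new("MarkerMatrix", dosage = rbind(dos, chk), map = cfg$map)
  } else genoAll <- geno

  sim <- simulateYield(genoAll, design, envs, cfg$truth, seed)
  tr <- simulateTraits(sim$plots, sim$truth, envs, cfg$panel, seed)
  sim$truth$traitLoadings <- tr$loadings
  sim$truth$crossPlan <- plan
  new("WheatTrial", plots = sim$plots, traits = tr$traits,
      panel = tr$panel, envs = envs, geno = geno, truth = sim$truth)
}

# Two-locations-by-two-years environment table with realistic UK winter
# wheat yield levels (t/ha); the second-year second location is the
# drought-limited low performer.
defaultEnvs <- function(n = 4) {
  all <- data.frame(
    env = c("Cam16", "Dux16", "Dux17", "Hinx17"),
    year = c(2016L, 2016L, 2017L, 2017L),
    location = c("Cambridge", "Duxford", "Duxford", "Hinxton"),
    mean = c(11.0, 11.8, 10.5, 8.8),
    stringsAsFactors = FALSE)
  if (n == 2) all[c(1, 2), ] else all[seq_len(n), ]
}

# Random cross plan: nCrosses parent sets (the last nThreeWay get a third
# parent), drawn so parents are reused across crosses as in an elite
# crossing programme.
crossPlan <- function(nParents, nCrosses, nThreeWay, seed) {
  set.seed(childSeed(seed, "plan"))
  ids <- sprintf("P%02d", seq_len(nParents))
  lapply(seq_len(nCrosses), function(i) {
    k <- if (i > nCrosses - nThreeWay) 3 else 2
    sample(ids, k)
  })
}
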