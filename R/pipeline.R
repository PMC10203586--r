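#' @include AllClasses.R
NULL

studyConfigKeys <- c("simulate", "data", "unit", "methods",
                     "predictorSets", "schemes", "k", "coKind", "lambda1",
                     "seed", "name")

# Stable short hash of a config list (for manifests): serialized JSON
# folded into a 32-bit sum.
configHash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                     digits = NA))
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

parseScheme <- function(s) {
  maskingScheme(type = s$type,
                fractions = if (!is.null(s$fractions))
                  unlist(s$fractions) else numeric(),
                trainEnvs = s$trainEnvs %||% character(),
                testEnvs = s$testEnvs %||% character(),
                supplementFraction = s$supplementFraction %||% 0.1,
                unit = s$unit %||% "plots",
                nReps = s$nReps %||% 100L,
                name = s$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a study configuration
#'
#' Schema check run before any stage: unknown keys are rejected, scheme
#' definitions are instantiated, and method/data compatibility is checked
#' (genomic BLUP without genotypes fails here, not mid-run).
#'
#' @param config study configuration list (or path to a YAML file).
#' @return the normalized configuration list, with schemes instantiated.
#' @export
validateStudyConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), studyConfigKeys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$simulate) && is.null(config$data))
    stop("config needs either a 'simulate' block or a 'data' path")
  config$unit <- config$unit %||% "plots"
  config$methods <- config$methods %||% "enet"
  config$predictorSets <- config$predictorSets %||% "traits"
  config$seed <- config$seed %||% 1L
  config$k <- config$k %||% 3L
  config$coKind <- config$coKind %||% "pco"
  config$lambda1 <- config$lambda1 %||% "cv"
  if (is.null(config$schemes)) stop("config needs at least one scheme")
  config$schemeObjects <- lapply(config$schemes, parseScheme)
  needGeno <- any(config$methods %in% c("gblup", "mv_gblup")) ||
    any(config$predictorSets %in% c("markers", "combined"))
  if (needGeno && is.null(config$simulate)) {
    gfiles <- file.path(config$data, c("genotypes.csv", "genotypes.vcf"))
    if (!any(file.exists(gfiles)))
      stop("genomic methods requested but no genotype file found in ",
           config$data)
  }
  if (any(config$methods %in% c("gblup", "mv_gblup")) &&
      config$unit != "line_blues")
    stop("gblup methods require unit 'line_blues'")
  config
}

#' Run a configured study end to end
#'
#' Orchestrates simulate (or load) -> marker QC -> BLUEs -> scheme
#' evaluation -> aggregation, writing each stage's outputs as CSV plus a
#' JSON manifest (config hash, seeds, stage timings). Reruns with an
#' identical configuration are bit-identical.
#'
#' @param config configuration list or YAML path; see
#'   [validateStudyConfig()] for the schema.
#' @param outDir output directory.
#' @return invisibly, a list with \code{records}, \code{summary},
#'   \code{qcReport} and the output paths.
#' @export
runStudy <- function(config, outDir) {
  cfg <- validateStudyConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  trial <- if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    simulateTrial(profile = sim$profile %||% "demo", seed = cfg$seed,
                  config = sim$config %||% list())
  } else readTrialCSV(cfg$data)
  writeTrialCSV(trial, file.path(outDir, "dataset"))
  timings$simulate <- tic() - t0

  t0 <- tic()
  study <- prepareStudy(trial, unit = cfg$unit)
  if (!is.null(study$qcReport)) {
    qc <- study$qcReport
    jsonlite::write_json(
      list(counts = as.list(qc@counts),
           nPruned = nrow(qc@pruned), flagged = qc@flagged),
      file.path(outDir, "qc_report.json"), auto_unbox = TRUE)
  }
  if (cfg$unit == "line_blues") {
    blues <- data.frame(id = study$units$id, env = study$units$env,
                        line = study$units$line, blue = study$y)
    utils::write.csv(blues, file.path(outDir, "blues.csv"),
                     row.names = FALSE)
  }
  timings$prepare <- tic() - t0

  t0 <- tic()
  records <- list()
  for (sc in cfg$schemeObjects) {
    for (m in cfg$methods) {
      psets <- if (m %in% c("gblup", "mv_gblup")) "markers"
               else cfg$predictorSets
      for (ps in psets) {
        records[[length(records) + 1L]] <-
          runScheme(study, method = m, predictorSet = ps, scheme = sc,
                    k = cfg$k, coKind = cfg$coKind,
                    lambda1 = cfg$lambda1, seed = cfg$seed)
      }
    }
  }
  records <- do.call(rbind, records)
  utils::write.csv(records, file.path(outDir, "records.csv"),
                   row.names = FALSE)
  summary <- aggregateRecords(records, environments(trial))
  utils::write.csv(summary, file.path(outDir, "summary.csv"),
                   row.names = FALSE)
  timings$evaluate <- tic() - t0

  cfgOut <- cfg[setdiff(names(cfg), "schemeObjects")]
  manifest <- list(config = cfgOut, configHash = configHash(cfgOut),
                   seed = cfg$seed, nRecords = nrow(records),
                   timingsSec = lapply(timings, round, 2))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(records = records, summary = summary,
                 qcReport = study$qcReport, outDir = outDir))
}

#' Write a self-contained fixture dataset bundle
#'
#' Generates one of the simulation profiles with a fixed seed and writes
#' the full CSV/VCF bundle (genotypes, design, plots, panel, truth);
#' regeneration with the same arguments is bit-identical.
#'
#' @param profile \code{"tiny"} (4 crosses x 10 lines, 50 markers, 2
#'   environments), \code{"demo"} (8 crosses x 40 lines, 300 markers, 4
#'   environments) or \code{"paper_shape"} (44 crosses x 68 lines = 2,992
#'   lines, 4 environments).
#' @param dir output directory.
#' @param seed integer seed (default 1).
#' @return the generated [WheatTrial-class], invisibly.
#' @export
makeFixture <- function(profile = c("tiny", "demo", "paper_shape"), dir,
                        seed = 1) {
  profile <- match.arg(profile)
  trial <- simulateTrial(profile, seed = seed)
  writeTrialCSV(trial, dir)
  invisible(trial)
}
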