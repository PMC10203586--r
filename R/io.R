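#' @include AllClasses.R
NULL

#' Write and read genotypes as CSV
#'
#' Lines x markers table with a header row of marker ids and the line id
#' in the first column; the interchange format between pipeline stages.
#'
#' @param x a [MarkerMatrix-class].
#' @param path output file.
#' @return \code{writeGenotypesCSV}: the path, invisibly.
#' @export
writeGenotypesCSV <- function(x, path) {
  d <- dosages(x)
  df <- data.frame(line = rownames(d), d, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGenotypesCSV
#' @param map optional genetic map for the markers; a placeholder map is
#'   built when omitted.
#' @return \code{readGenotypesCSV}: a [MarkerMatrix-class].
#' @export
readGenotypesCSV <- function(path, map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df[[1]]
  markerMatrix(d, map)
}

#' Write and read genotypes as minimal VCF with DS dosages
#'
#' A minimal VCF 4.2 dialect: one record per marker with the dosage in the
#' per-sample DS (posterior dosage) FORMAT field, the genetic-map
#' chromosome as CHROM and the cM position (x 10000, integer) as POS.
#' Missing dosages are written as ".".
#'
#' @param x a [MarkerMatrix-class].
#' @param path output file (plain text, uncompressed).
#' @return \code{writeGenotypesVCF}: the path, invisibly.
#' @export
writeGenotypesVCF <- function(x, path) {
  d <- dosages(x)
  map <- markerMap(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=phenogs",
               paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                      "Description=\"Pooled dosage of ALT allele\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(d)),
                     collapse = "\t")), con)
  body <- vapply(seq_len(ncol(d)), function(j) {
    ds <- ifelse(is.na(d[, j]), ".", formatC(d[, j], format = "g",
                                             digits = 10))
    paste(c(map$chrom[j], as.integer(round(map$pos[j] * 1e4)),
            map$marker[j], "A", "B", ".", "PASS", ".", "DS", ds),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname writeGenotypesVCF
#' @return \code{readGenotypesVCF}: a [MarkerMatrix-class].
#' @export
readGenotypesVCF <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    d <- t(ds)
    map <- data.frame(marker = rownames(ds),
                      chrom = as.integer(v@fix[, "CHROM"]),
                      pos = as.numeric(v@fix[, "POS"]) / 1e4,
                      stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path)
    hdr <- ln[startsWith(ln, "#CHROM")]
    samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
    rows <- strsplit(ln[!startsWith(ln, "#")], "\t")
    map <- data.frame(
      marker = vapply(rows, `[`, "", 3),
      chrom = as.integer(vapply(rows, `[`, "", 1)),
      pos = as.numeric(vapply(rows, `[`, "", 2)) / 1e4,
      stringsAsFactors = FALSE)
    d <- t(vapply(rows, function(r)
      suppressWarnings(as.numeric(r[-(1:9)])), numeric(length(samples))))
    rownames(d) <- map$marker
    colnames(d) <- samples
    d <- t(d)
  }
  markerMatrix(d, map)
}

#' Write a trial to a directory of CSV files
#'
#' Writes \code{plots.csv} (design columns, moisture, raw and adjusted
#' yield, then one column per trait), \code{panel.csv}, \code{envs.csv},
#' \code{genotypes.csv}, \code{genotypes.vcf} and -- for simulated trials
#' -- \code{truth_genetic_values.csv}.
#'
#' @param trial a [WheatTrial-class].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeTrialCSV <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plots <- cbind(plotTable(trial), as.data.frame(traitValues(trial)))
  utils::write.csv(plots, file.path(dir, "plots.csv"), row.names = FALSE)
  utils::write.csv(traitPanel(trial), file.path(dir, "panel.csv"),
                   row.names = FALSE)
  utils::write.csv(environments(trial), file.path(dir, "envs.csv"),
                   row.names = FALSE)
  if (!is.null(genotypes(trial))) {
    writeGenotypesCSV(genotypes(trial), file.path(dir, "genotypes.csv"))
    writeGenotypesVCF(genotypes(trial), file.path(dir, "genotypes.vcf"))
  }
  tr <- simTruth(trial)
  if (length(tr)) {
    g <- data.frame(line = rownames(tr$g), u = tr$u, tr$g,
                    check.names = FALSE)
    utils::write.csv(g, file.path(dir, "truth_genetic_values.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a trial from a directory of CSV files
#'
#' Ingestion path for real or previously written data: expects the file
#' layout of [writeTrialCSV()] (\code{truth_genetic_values.csv} optional;
#' genotypes optional, CSV preferred over VCF when both exist).
#'
#' @param dir directory containing the trial files.
#' @return A [WheatTrial-class].
#' @export
readTrialCSV <- function(dir) {
  plots <- utils::read.csv(file.path(dir, "plots.csv"),
                           check.names = FALSE)
  panel <- utils::read.csv(file.path(dir, "panel.csv"),
                           check.names = FALSE,
                           colClasses = c(trait = "character"))
  envs <- utils::read.csv(file.path(dir, "envs.csv"), check.names = FALSE)
  design <- plots[, c("plot", "env", "block", "subBlock", "line",
                      "isCheck", "moisture", "yieldRaw", "yield")]
  traits <- as.matrix(plots[, panel$trait, drop = FALSE])
  geno <- NULL
  if (file.exists(file.path(dir, "genotypes.csv")))
    geno <- readGenotypesCSV(file.path(dir, "genotypes.csv"))
  else if (file.exists(file.path(dir, "genotypes.vcf")))
    geno <- readGenotypesVCF(file.path(dir, "genotypes.vcf"))
  new("WheatTrial", plots = design, traits = traits, panel = panel,
      envs = envs, geno = geno, truth = list())
}
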