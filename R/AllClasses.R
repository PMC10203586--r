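#' @import methods
#' @importFrom stats cor sd var rnorm runif rbinom setNames na.omit coef
NULL

#' MarkerMatrix: lines x markers dosage table with a genetic map
#'
#' Container for SNP dosages of a line panel. Dosages count copies of the
#' alternate allele and live in [0, 2]; fractional values are legitimate and
#' arise from codominant scoring of pooled DNA (several sibling plants bulked
#' per line). Missing values are allowed and encoded as \code{NA}. The genetic
#' map records, per marker, the chromosome and position in centiMorgans; it is
#' consumed only by the meiosis simulator, not by any prediction model.
#'
#' @slot dosage numeric matrix, lines in rows (rownames = line ids), markers in
#'   columns (colnames = marker ids), values in [0, 2] or \code{NA}.
#' @slot map data.frame with columns \code{marker}, \code{chrom}, \code{pos}
#'   (cM), one row per dosage column in the same order.
#'
#' @seealso [markerMatrix()], [simulateFounders()], [makeCross()]
#' @export
setClass("MarkerMatrix",
  representation(dosage = "matrix", map = "data.frame"))

setValidity("MarkerMatrix", function(object) {
  d <- object@dosage
  msg <- character()
  if (nrow(d) && (is.null(rownames(d)) || anyDuplicated(rownames(d))))
    msg <- c(msg, "line ids must be present and unique")
  if (ncol(d) && (is.null(colnames(d)) || anyDuplicated(colnames(d))))
    msg <- c(msg, "marker ids must be present and unique")
  v <- d[!is.na(d)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  m <- object@map
  if (!all(c("marker", "chrom", "pos") %in% names(m)))
    msg <- c(msg, "map needs columns marker, chrom, pos")
  else if (ncol(d) && !identical(as.character(m$marker), colnames(d)))
    msg <- c(msg, "map rows must match dosage columns in order")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerMatrix
#'
#' @param dosage numeric matrix (lines x markers) with dimnames.
#' @param map optional genetic map data.frame (\code{marker}, \code{chrom},
#'   \code{pos}); a single-chromosome placeholder map is built when omitted.
#' @return A [MarkerMatrix-class] object.
#' @export
markerMatrix <- function(dosage, map = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(map)) {
    map <- data.frame(marker = colnames(dosage), chrom = 1L,
                      pos = seq_len(ncol(dosage)), stringsAsFactors = FALSE)
  }
  new("MarkerMatrix", dosage = dosage, map = map)
}

#' WheatTrial: a multi-environment trial dataset
#'
#' Bundles everything one study cycle needs: the plot table (design factors,
#' grain moisture, raw and dry-matter-adjusted yield), the plot x trait value
#' matrix, the trait panel metadata (category and time point per trait), the
#' environment table, the line genotypes and -- for simulated data -- the
#' generating truth (genetic values, variance components, loadings).
#'
#' @slot plots data.frame with columns \code{plot}, \code{env}, \code{block},
#'   \code{subBlock}, \code{line}, \code{isCheck}, \code{moisture} (\%),
#'   \code{yieldRaw} and \code{yield} (t/ha at 85\% dry matter).
#' @slot traits numeric matrix, one row per plot (same order as \code{plots}),
#'   one column per trait; \code{NA} marks traits not scored in a year.
#' @slot panel data.frame with columns \code{trait}, \code{category}
#'   (multispectral / hyperspectral / visual / soil), \code{timePoint},
#'   \code{group} (redundancy group, simulated data only).
#' @slot envs data.frame with columns \code{env}, \code{year},
#'   \code{location}, \code{mean} (t/ha).
#' @slot geno a [MarkerMatrix-class] or \code{NULL}.
#' @slot truth list of simulation ground truth (empty for ingested data).
#' @export
setClass("WheatTrial",
  representation(plots = "data.frame", traits = "matrix",
                 panel = "data.frame", envs = "data.frame",
                 geno = "ANY", truth = "list"))

setValidity("WheatTrial", function(object) {
  msg <- character()
  need <- c("plot", "env", "block", "subBlock", "line", "isCheck",
            "moisture", "yieldRaw", "yield")
  if (!all(need %in% names(object@plots)))
    msg <- c(msg, paste("plots needs columns:", paste(need, collapse = ", ")))
  if (nrow(object@traits) && nrow(object@traits) != nrow(object@plots))
    msg <- c(msg, "traits must have one row per plot")
  if (ncol(object@traits) &&
      !identical(colnames(object@traits), as.character(object@panel$trait)))
    msg <- c(msg, "every trait column needs exactly one panel entry, in order")
  if (anyDuplicated(object@envs$env))
    msg <- c(msg, "environment ids must be unique")
  ok <- !is.na(object@plots$yield)
  if (any(object@plots$yield[ok] < 0))
    msg <- c(msg, "yield must be non-negative")
  mo <- object@plots$moisture
  mo <- mo[!is.na(mo)]
  if (length(mo) && (min(mo) < 0 || max(mo) > 100))
    msg <- c(msg, "moisture must lie in [0, 100]")
  if (!is.null(object@geno) && !is(object@geno, "MarkerMatrix"))
    msg <- c(msg, "geno must be a MarkerMatrix or NULL")
  if (length(msg)) msg else TRUE
})

#' QCReport: bookkeeping for the marker filtering chain
#'
#' Records marker counts at each stage of the QC chain (input, imputation,
#' PIC filter, correlation pruning), per-marker PIC values, and for every
#' pruned marker the retained anchor it was correlated with.
#'
#' @slot counts named integer vector of marker counts per completed stage.
#' @slot pic named numeric vector of PIC values (post-imputation markers).
#' @slot pruned data.frame with columns \code{marker}, \code{anchor}, \code{r}.
#' @slot flagged character, markers flagged (all-missing or zero-variance).
#' @export
setClass("QCReport",
  representation(counts = "integer", pic = "numeric",
                 pruned = "data.frame", flagged = "character"))

setValidity("QCReport", function(object) {
  if (is.unsorted(rev(object@counts)))
    "stage counts must be non-increasing along the chain" else TRUE
})

#' ComponentSet: PCA or PLS reduction of a trait panel
#'
#' @slot kind \code{"PCO"} or \code{"PLS"}.
#' @slot scores observations x components score matrix.
#' @slot loadings traits x components loading matrix.
#' @slot yieldCor per-component Pearson correlation with yield.
#' @slot categoryShare trait-category x component matrix of squared-loading
#'   shares (columns sum to 1).
#' @slot dominant list, per component the categories contributing > 25\% of
#'   squared loading mass (a reporting convention).
#' @export
setClass("ComponentSet",
  representation(kind = "character", scores = "matrix", loadings = "matrix",
                 yieldCor = "numeric", categoryShare = "matrix",
                 dominant = "list"))

#' MaskingScheme: which units are masked, where, how often
#'
#' Declarative description of one resampling scheme. Three families are
#' supported: \code{"fraction"} (per-environment training fractions from the
#' grid 1/0.75/0.5/0.25/0.15/0.10/0.05/0), \code{"whole_location"} (explicit
#' training and test environment sets), and \code{"supplement"}
#' (whole-location training plus a stated random fraction of the test
#' location).
#'
#' @slot type one of \code{"fraction"}, \code{"whole_location"},
#'   \code{"supplement"}.
#' @slot fractions named numeric, training fraction per environment
#'   (fraction type).
#' @slot trainEnvs,testEnvs character environment ids (whole-location and
#'   supplement types).
#' @slot supplementFraction numeric in [0, 1] (supplement type).
#' @slot unit \code{"plots"} or \code{"line_blues"}.
#' @slot nReps number of resampling replicates.
#' @slot name scheme label used in accuracy records.
#' @export
setClass("MaskingScheme",
  representation(type = "character", fractions = "numeric",
                 trainEnvs = "character", testEnvs = "character",
                 supplementFraction = "numeric", unit = "character",
                 nReps = "integer", name = "character"))

setValidity("MaskingScheme", function(object) {
  msg <- character()
  if (!object@type %in% c("fraction", "whole_location", "supplement"))
    msg <- c(msg, "unknown scheme type")
  if (!object@unit %in% c("plots", "line_blues"))
    msg <- c(msg, "unit must be 'plots' or 'line_blues'")
  if (object@type == "fraction") {
    f <- object@fractions
    if (!length(f) || is.null(names(f)))
      msg <- c(msg, "fraction scheme needs named per-environment fractions")
    else if (any(f < 0 | f > 1))
      msg <- c(msg, "fractions must lie in [0, 1]")
    else if (all(f == 0))
      msg <- c(msg, "at least one training fraction must be positive")
  } else {
    if (!length(object@trainEnvs) || !length(object@testEnvs))
      msg <- c(msg, "whole-location schemes need train and test environments")
    if (length(intersect(object@trainEnvs, object@testEnvs)))
      msg <- c(msg, "train and test environments must be disjoint")
  }
  if (object@type == "supplement" &&
      (object@supplementFraction <= 0 || object@supplementFraction >= 1))
    msg <- c(msg, "supplementFraction must lie in (0, 1)")
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a MaskingScheme
#'
#' @param type scheme family: \code{"fraction"}, \code{"whole_location"} or
#'   \code{"supplement"}.
#' @param fractions named numeric vector of per-environment training
#'   fractions (fraction schemes).
#' @param trainEnvs,testEnvs environment id vectors (whole-location and
#'   supplement schemes).
#' @param supplementFraction fraction of test-location units added to
#'   training (supplement schemes). Default 0.1.
#' @param unit resampling unit: raw \code{"plots"} or \code{"line_blues"}.
#' @param nReps number of resampling replicates (default 100).
#' @param name scheme label; autogenerated when omitted.
#' @return A [MaskingScheme-class] object.
#' @export
maskingScheme <- function(type = c("fraction", "whole_location", "supplement"),
                          fractions = numeric(), trainEnvs = character(),
                          testEnvs = character(), supplementFraction = 0.1,
                          unit = c("plots", "line_blues"), nReps = 100L,
                          name = NULL) {
  type <- match.arg(type)
  unit <- match.arg(unit)
  if (is.null(name)) {
    name <- switch(type,
      fraction = paste0("frac[", paste(names(fractions), fractions,
                                       sep = "=", collapse = ","), "]"),
      whole_location = paste0("loc[", paste(trainEnvs, collapse = "+"),
                              "->", paste(testEnvs, collapse = "+"), "]"),
      supplement = paste0("supp[", paste(trainEnvs, collapse = "+"), "+",
                          supplementFraction, "*",
                          paste(testEnvs, collapse = "+"), "]"))
  }
  new("MaskingScheme", type = type, fractions = fractions,
      trainEnvs = as.character(trainEnvs), testEnvs = as.character(testEnvs),
      supplementFraction = supplementFraction, unit = unit,
      nReps = as.integer(nReps), name = name)
}

#' PenalizedFit: a fitted penalized linear model
#'
#' Stores the intercept and coefficients on the standardized predictor scale
#' together with the standardization parameters, so that prediction on new
#' data reproduces the training-time transform exactly.
#'
#' @slot intercept numeric, on the (possibly transformed) response scale.
#' @slot coef named numeric coefficient vector (standardized scale).
#' @slot transform list from [standardizeXY()]: per-predictor center/scale,
#'   response center/scale (global or per environment), dropped columns.
#' @slot spec list: \code{lambda1}, \code{lambda2}, \code{label}.
#' @slot meta list: iterations, converged flag, predictor set tag, selected
#'   lambda1 path details when chosen by internal cross-validation.
#' @export
setClass("PenalizedFit",
  representation(intercept = "numeric", coef = "numeric",
                 transform = "list", spec = "list", meta = "list"))
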