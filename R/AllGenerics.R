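#' @include AllClasses.R
NULL

#' Accessors for MarkerMatrix and WheatTrial objects
#'
#' Small accessor family in the Bioconductor idiom: prefer these to direct
#' slot access.
#'
#' @param x a [MarkerMatrix-class] or [WheatTrial-class] object.
#' @return \code{dosages}: the numeric dosage matrix; \code{markerMap}: the
#'   genetic map data.frame; \code{lineIds}/\code{markerIds}: character ids;
#'   \code{nLines}/\code{nMarkers}: integer counts; \code{plotTable}: the
#'   plot-level data.frame; \code{traitValues}: plots x traits matrix;
#'   \code{traitPanel}: trait metadata; \code{environments}: environment
#'   table; \code{genotypes}: the trial's MarkerMatrix (or NULL);
#'   \code{simTruth}: the simulation ground-truth list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "MarkerMatrix", function(x) x@dosage)

#' @rdname accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @rdname accessors
#' @export
setMethod("markerMap", "MarkerMatrix", function(x) x@map)

#' @rdname accessors
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))
#' @rdname accessors
#' @export
setMethod("lineIds", "MarkerMatrix", function(x) rownames(x@dosage))

#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setMethod("markerIds", "MarkerMatrix", function(x) colnames(x@dosage))

#' @rdname accessors
#' @export
setGeneric("nLines", function(x) standardGeneric("nLines"))
#' @rdname accessors
#' @export
setMethod("nLines", "MarkerMatrix", function(x) nrow(x@dosage))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname accessors
#' @export
setMethod("nMarkers", "MarkerMatrix", function(x) ncol(x@dosage))

#' Subset a MarkerMatrix by lines and/or markers
#'
#' @param x a [MarkerMatrix-class].
#' @param i line index (integer, logical or line ids).
#' @param j marker index (integer, logical or marker ids).
#' @param ... ignored.
#' @param drop ignored; the result is always a MarkerMatrix.
#' @export
setMethod("[", "MarkerMatrix", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosage
  if (missing(i)) i <- seq_len(nrow(d))
  if (missing(j)) j <- seq_len(ncol(d))
  d <- d[i, j, drop = FALSE]
  map <- x@map[match(colnames(d), x@map$marker), , drop = FALSE]
  rownames(map) <- NULL
  new("MarkerMatrix", dosage = d, map = map)
})

#' @rdname accessors
#' @export
setGeneric("plotTable", function(x) standardGeneric("plotTable"))
#' @rdname accessors
#' @export
setMethod("plotTable", "WheatTrial", function(x) x@plots)

#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))
#' @rdname accessors
#' @export
setMethod("traitValues", "WheatTrial", function(x) x@traits)

#' @rdname accessors
#' @export
setGeneric("traitPanel", function(x) standardGeneric("traitPanel"))
#' @rdname accessors
#' @export
setMethod("traitPanel", "WheatTrial", function(x) x@panel)

#' @rdname accessors
#' @export
setGeneric("environments", function(x) standardGeneric("environments"))
#' @rdname accessors
#' @export
setMethod("environments", "WheatTrial", function(x) x@envs)

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setMethod("genotypes", "WheatTrial", function(x) x@geno)

#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setMethod("simTruth", "WheatTrial", function(x) x@truth)

setMethod("show", "MarkerMatrix", function(object) {
  d <- object@dosage
  cat("MarkerMatrix:", nrow(d), "lines x", ncol(d), "markers\n")
  cat("  chromosomes:", length(unique(object@map$chrom)),
      " missing:", sum(is.na(d)), "\n")
  frac <- mean(!is.na(d) & d %% 1 != 0)
  cat(sprintf("  fractional (pooled) dosages: %.1f%%\n", 100 * frac))
})

setMethod("show", "WheatTrial", function(object) {
  cat("WheatTrial:", nrow(object@plots), "plots,",
      length(unique(object@plots$line)), "lines,",
      nrow(object@envs), "environments\n")
  if (ncol(object@traits)) {
    tab <- table(object@panel$category)
    cat("  traits:", ncol(object@traits), "(",
        paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
  }
  if (!is.null(object@geno))
    cat("  genotypes:", nMarkers(object@geno), "markers\n")
  if (length(object@truth)) cat("  simulation truth attached\n")
})

setMethod("show", "QCReport", function(object) {
  cat("Marker QC report\n")
  for (nm in names(object@counts))
    cat(sprintf("  %-16s %d\n", nm, object@counts[[nm]]))
  if (nrow(object@pruned))
    cat("  pruned:", nrow(object@pruned), "markers (anchors recorded)\n")
  if (length(object@flagged))
    cat("  flagged:", length(object@flagged), "markers\n")
})

setMethod("show", "ComponentSet", function(object) {
  cat(object@kind, "component set:", ncol(object@scores), "components on",
      nrow(object@loadings), "traits\n")
  cat("  cor with yield:",
      paste(sprintf("%.3f", object@yieldCor), collapse = ", "), "\n")
})

setMethod("show", "MaskingScheme", function(object) {
  cat("MaskingScheme", object@name, "\n")
  cat("  type:", object@type, " unit:", object@unit,
      " reps:", object@nReps, "\n")
})

setMethod("show", "PenalizedFit", function(object) {
  nz <- sum(object@coef != 0)
  cat(sprintf("PenalizedFit (%s): %d/%d non-zero coefficients\n",
              object@spec$label, nz, length(object@coef)))
  cat(sprintf("  lambda1 = %g, lambda2 = %g, converged = %s\n",
              object@spec$lambda1, object@spec$lambda2,
              isTRUE(object@meta$converged)))
})
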