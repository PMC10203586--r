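#' @include AllClasses.R
NULL

#' Mean-impute missing marker dosages
#'
#' Replaces each missing dosage by the marker's observed mean (a simple
#' stand-in for haplotype-based imputation; adequate for sporadic
#' missingness). Markers with no observed value cannot be imputed and are
#' dropped with a warning.
#'
#' @param x a [MarkerMatrix-class].
#' @return A [MarkerMatrix-class] with no missing values; dropped markers
#'   are recorded in \code{attr(, "dropped")}.
#' @export
imputeMean <- function(x) {
  stopifnot(is(x, "MarkerMatrix"))
  d <- dosages(x)
  allMiss <- colSums(!is.na(d)) == 0
  if (any(allMiss)) {
    warning(sum(allMiss), " fully missing marker(s) dropped: ",
            paste(utils::head(colnames(d)[allMiss], 5), collapse = ", "))
    d <- d[, !allMiss, drop = FALSE]
  }
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2]]
  out <- markerMatrix(d, markerMap(x)[match(colnames(d),
                                            markerMap(x)$marker), ])
  attr(out, "dropped") <- colnames(dosages(x))[allMiss]
  out
}

#' Polymorphism information content of a biallelic marker
#'
#' PIC = 1 - (p^2 + q^2) - 2 p^2 q^2 with q = 1 - p.
#'
#' @param alleleFreq allele frequency in [0, 1] (vectorized).
#' @return PIC value(s) in [0, 0.375].
#' @examples
#' pic(0.5)  # 0.375
#' @export
pic <- function(alleleFreq) {
  if (any(alleleFreq < 0 | alleleFreq > 1))
    stop("allele frequency must lie in [0, 1]")
  p <- alleleFreq; q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Filter markers by PIC
#'
#' Retains markers whose PIC is strictly greater than the threshold. Allele
#' frequency is estimated as mean dosage / 2, which remains valid for
#' fractional pooled scores.
#'
#' @param x a [MarkerMatrix-class] with no missing dosages (run
#'   [imputeMean()] first).
#' @param threshold PIC threshold (default 0.1, markers with PIC > 0.1 kept).
#' @return list with \code{markers} (filtered [MarkerMatrix-class]) and
#'   \code{pic} (named PIC vector for all input markers).
#' @export
filterPIC <- function(x, threshold = 0.1) {
  stopifnot(is(x, "MarkerMatrix"))
  d <- dosages(x)
  if (anyNA(d)) stop("dosages must be imputed before PIC filtering")
  p <- colMeans(d) / 2
  v <- pic(p)
  names(v) <- colnames(d)
  keep <- v > threshold
  if (!any(keep)) warning("no marker exceeds the PIC threshold")
  list(markers = x[, keep, drop = FALSE], pic = v)
}

#' Greedy correlation pruning of redundant markers
#'
#' Single pass in the given order: a marker is dropped when its correlation
#' with any already-retained marker exceeds the threshold (absolute
#' correlation by default; \code{signed = TRUE} prunes on positive r only).
#' Zero-variance markers correlate with nothing, are retained and flagged.
#'
#' @param x a [MarkerMatrix-class] with no missing dosages.
#' @param rThreshold correlation threshold (default 0.9; r strictly greater
#'   prunes).
#' @param order \code{"input"} (map order) or \code{"pic_desc"} (most
#'   informative markers anchored first). Retained sets differ between the
#'   two.
#' @param signed prune on signed r instead of |r| (default FALSE).
#' @return list with \code{markers} (pruned [MarkerMatrix-class], original
#'   column order), \code{pruned} (data.frame: marker, anchor, r) and
#'   \code{flagged} (zero-variance markers).
#' @export
pruneCorrelated <- function(x, rThreshold = 0.9,
                            order = c("input", "pic_desc"), signed = FALSE) {
  stopifnot(is(x, "MarkerMatrix"))
  order <- match.arg(order)
  d <- dosages(x)
  if (anyNA(d)) stop("dosages must be imputed before pruning")
  m <- ncol(d)
  if (m < 2) stop("pruning needs at least two markers")
  sds <- apply(d, 2, stats::sd)
  flagged <- colnames(d)[sds == 0]
  ord <- seq_len(m)
  if (order == "pic_desc")
    ord <- ord[base::order(pic(colMeans(d) / 2), decreasing = TRUE)]
  # center/scale once; zero-variance columns stay zero (correlate with
  # nothing by convention)
  Z <- scale(d)
  Z[, sds == 0] <- 0
  n1 <- nrow(d) - 1
  kept <- integer(0)
  drops <- list()
  for (j in ord) {
    if (length(kept)) {
      r <- as.numeric(crossprod(Z[, kept, drop = FALSE], Z[, j])) / n1
      rr <- if (signed) r else abs(r)
      hit <- which(rr > rThreshold)
      if (length(hit)) {
        a <- kept[hit[which.max(rr[hit])]]
        drops[[length(drops) + 1L]] <-
          data.frame(marker = colnames(d)[j], anchor = colnames(d)[a],
                     r = r[hit[which.max(rr[hit])]],
                     stringsAsFactors = FALSE)
        next
      }
    }
    kept <- c(kept, j)
  }
  pruned <- if (length(drops)) do.call(rbind, drops)
            else data.frame(marker = character(), anchor = character(),
                            r = numeric(), stringsAsFactors = FALSE)
  list(markers = x[, sort(kept), drop = FALSE], pruned = pruned,
       flagged = flagged)
}

#' Full marker QC chain
#'
#' Imputation of sporadic missing dosages, PIC filtering (strictly greater
#' than the threshold), then greedy correlation pruning -- in that order.
#'
#' @param x a [MarkerMatrix-class].
#' @param picThreshold PIC threshold (default 0.1).
#' @param rThreshold correlation pruning threshold (default 0.9).
#' @param order pruning order, see [pruneCorrelated()].
#' @param signed prune on signed r, see [pruneCorrelated()].
#' @return list with \code{markers} (the QC'd [MarkerMatrix-class]) and
#'   \code{report} (a [QCReport-class]).
#' @export
markerQC <- function(x, picThreshold = 0.1, rThreshold = 0.9,
                     order = "input", signed = FALSE) {
  stopifnot(is(x, "MarkerMatrix"))
  imp <- imputeMean(x)
  fp <- filterPIC(imp, picThreshold)
  pr <- if (ncol(dosages(fp$markers)) >= 2) {
    pruneCorrelated(fp$markers, rThreshold, order = order, signed = signed)
  } else {
    list(markers = fp$markers,
         pruned = data.frame(marker = character(), anchor = character(),
                             r = numeric(), stringsAsFactors = FALSE),
         flagged = character())
  }
  report <- new("QCReport",
    counts = c(input = ncol(dosages(x)),
               imputed = ncol(dosages(imp)),
               pic_filtered = ncol(dosages(fp$markers)),
               pruned = ncol(dosages(pr$markers))),
    pic = fp$pic, pruned = pr$pruned,
    flagged = c(attr(imp, "dropped"), pr$flagged))
  list(markers = pr$markers, report = report)
}
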