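#' Whittaker pairwise dissimilarity of two binary marker profiles
#'
#' The pairwise beta-diversity measure used to compare TBP fingerprints:
#' \deqn{\beta_W = S/\bar\alpha - 1}
#' where \eqn{S} is the number of markers present in the union of the pair
#' and \eqn{\bar\alpha} the mean per-sample marker count. On binary profiles
#' with \eqn{a} shared and \eqn{b}, \eqn{c} private markers this equals
#' \eqn{(b+c)/(2a+b+c)}: 0 for identical presence sets, 1 for disjoint ones.
#'
#' @param x,y binary (0/1) vectors of equal length, each with at least one
#'   presence.
#' @return dissimilarity in [0, 1].
#' @examples
#' whittakerPairwise(c(1, 1, 0), c(1, 0, 1))   # a=1, b=1, c=1 -> 0.5
#' @export
whittakerPairwise <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("profiles differ in length")
  if (!all(c(x, y) %in% c(0, 1))) stop("profiles must be binary 0/1")
  if (sum(x) == 0 || sum(y) == 0)
    stop("Whittaker index is undefined for an all-zero profile")
  S <- sum(x + y > 0)
  alphaBar <- (sum(x) + sum(y)) / 2
  S / alphaBar - 1
}

#' Pairwise Whittaker dissimilarity matrix
#'
#' @param m a [MarkerMatrix-class] (>= 2 samples) or a binary
#'   samples-x-markers matrix with row names. NA cells (samples missing a
#'   region) are not allowed here; combine with \code{missing = "drop"}.
#' @return a \code{\link[stats]{dist}} with \code{method = "whittaker"},
#'   zero diagonal and entries in [0, 1].
#' @export
whittakerDist <- function(m) {
  x <- .sampleRows(m)
  if (nrow(x) < 2L) stop("need >= 2 samples")
  if (anyNA(x))
    stop("NA cells present; use combineRegions(..., missing = 'drop')")
  zero <- rownames(x)[rowSums(x) == 0]
  if (length(zero))
    stop("all-zero marker profile for sample(s): ",
         paste(zero, collapse = ", "))
  # (b+c)/(2a+b+c) = (ri + rj - 2a) / (ri + rj), vectorized over all pairs
  A <- tcrossprod(x)
  r <- rowSums(x)
  denom <- outer(r, r, `+`)
  D <- (denom - 2 * A) / denom
  diag(D) <- 0
  dimnames(D) <- list(rownames(x), rownames(x))
  stats::as.dist(D)
}

#' Shannon diversity of a marker group
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over the markers of a sample group. The
#' basis of \eqn{p_i} is an explicit, required convention:
#' \code{"presence-frequency"} sets \eqn{p_i} to the number of samples in
#' the group carrying marker \eqn{i} divided by the total number of marker
#' presences in the group. The argument has no default so a conventional
#' choice is never made silently.
#'
#' @param m a [MarkerMatrix-class] or binary samples-x-markers matrix.
#' @param convention frequency convention; currently
#'   \code{"presence-frequency"}.
#' @param samples optional character vector restricting the group.
#' @return Shannon index H (natural log), >= 0.
#' @examples
#' m <- matrix(1, 2, 5, dimnames = list(c("A", "B"), NULL))
#' shannonIndex(m, "presence-frequency")   # uniform over 5 markers: ln 5
#' @export
shannonIndex <- function(m, convention, samples = NULL) {
  convention <- match.arg(convention, "presence-frequency")
  x <- .sampleRows(m)
  if (!is.null(samples)) {
    bad <- setdiff(samples, rownames(x))
    if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
    x <- x[samples, , drop = FALSE]
  }
  counts <- colSums(x, na.rm = TRUE)
  tot <- sum(counts)
  if (tot == 0) stop("group has no marker presences")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Intra/inter-specific partition of a dissimilarity matrix (barcoding gap)
#'
#' Splits all pairwise dissimilarities into intra-specific pairs (same
#' species label) and inter-specific pairs, reports both ranges, and
#' quantifies the barcoding-gap overlap: the fraction of all observations
#' (intra or inter) falling in the closed interval
#' [min(inter), max(intra)], 0 when max(intra) < min(inter) (a perfect gap).
#'
#' @param d a \code{dist} (e.g. from [whittakerDist()]).
#' @param metadata data.frame with \code{SampleCode} and \code{Species}
#'   covering every sample in \code{d}; >= 2 species, at least one species
#'   with >= 2 samples.
#' @return list of class \code{"tbpGap"}: \code{intra}, \code{inter}
#'   (value vectors), \code{intraRange}, \code{interRange},
#'   \code{overlapFraction}, \code{overlapPercent}, \code{pairs}
#'   (data.frame sample1, sample2, type, value).
#' @export
partitionIntraInter <- function(d, metadata) {
  stopifnot(inherits(d, "dist"))
  labs <- attr(d, "Labels")
  if (is.null(labs)) stop("dissimilarity matrix has no sample labels")
  checkSampleCodes(labs, metadata)
  sp <- metadata$Species[match(labs, metadata$SampleCode)]
  if (any(is.na(sp) | sp == ""))
    stop("every sample needs a non-empty species label")
  if (length(unique(sp)) < 2L) stop("need >= 2 species")
  n <- length(labs)
  v <- as.vector(d)
  # as.vector(dist) is column-major lower triangle: entry (j, i) for j > i
  i2 <- unlist(lapply(seq_len(n - 1), function(k) rep(k, n - k)))
  j2 <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  type <- ifelse(sp[i2] == sp[j2], "intra", "inter")
  pairs <- data.frame(sample1 = labs[i2], sample2 = labs[j2],
                      type = type, value = v)
  intra <- v[type == "intra"]; inter <- v[type == "inter"]
  if (!length(intra))
    stop("no intra-specific pairs: need a species with >= 2 samples")
  lo <- min(inter); hi <- max(intra)
  overlap <- if (hi < lo) 0 else mean(v >= lo & v <= hi)
  structure(list(intra = intra, inter = inter,
                 intraRange = range(intra), interRange = range(inter),
                 overlapFraction = overlap,
                 overlapPercent = 100 * overlap, pairs = pairs),
            class = "tbpGap")
}

#' @export
print.tbpGap <- function(x, ...) {
  cat("Barcoding-gap analysis (Whittaker dissimilarities)\n")
  cat(sprintf("  intra-specific: n = %d, range %.3f - %.3f\n",
              length(x$intra), x$intraRange[1], x$intraRange[2]))
  cat(sprintf("  inter-specific: n = %d, range %.3f - %.3f\n",
              length(x$inter), x$interRange[1], x$interRange[2]))
  cat(sprintf("  overlap: %.2f%% of observations in [min inter, max intra]\n",
              x$overlapPercent))
  invisible(x)
}
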