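# gap-cut single-linkage clustering of a sorted numeric vector:
# returns integer cluster ids (1-based, ascending)
.gapCluster <- function(sizes, gapTol) {
  if (!length(sizes)) return(integer(0))
  cumsum(c(1, diff(sizes) > gapTol))
}

#' Bin consensus peaks of one intron region into markers
#'
#' All (sample, size) pairs of one region are pooled and sorted ascending;
#' a new bin starts wherever the gap to the previous size exceeds
#' \code{gapTolBp} (single-linkage chaining with a gap cut). Each bin is one
#' marker; its presence/absence across samples fills a binary
#' [MarkerMatrix-class]. If one sample contributes two or more peaks to a
#' single bin they collapse to one presence with a collision warning (the
#' matrix is presence/absence by definition). Bins whose span exceeds twice
#' the tolerance trigger a chaining warning.
#'
#' @param profiles list of [ConsensusProfile-class], all of the same region
#'   (profiles with status \code{"no_data"} are rejected).
#' @param gapTolBp gap tolerance in bp (> 0), default 1.0.
#' @return a [MarkerMatrix-class] for the region; samples in input order.
#' @examples
#' pA <- ConsensusProfile("A", "first",
#'         data.frame(size = c(302.1, 450.0), support = 4, meanHeight = 1e3))
#' pB <- ConsensusProfile("B", "first",
#'         data.frame(size = c(302.8, 455.2), support = 4, meanHeight = 1e3))
#' presence(binMarkers(list(pA, pB)))
#' @export
binMarkers <- function(profiles, gapTolBp = 1.0) {
  if (!(is.numeric(gapTolBp) && gapTolBp > 0))
    stop("gapTolBp must be > 0")
  stopifnot(all(vapply(profiles, is, logical(1), "ConsensusProfile")))
  samples <- vapply(profiles, sampleCode, character(1))
  if (anyDuplicated(samples))
    stop("duplicate sample codes among profiles: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  regions <- unique(vapply(profiles, intronRegion, character(1)))
  if (length(profiles) && length(regions) != 1L)
    stop("all profiles must belong to one intron region")
  region <- if (length(profiles)) regions else "first"

  pool <- do.call(rbind, lapply(profiles, function(p) {
    pk <- profilePeaks(p)
    if (!nrow(pk)) return(NULL)
    data.frame(sample = sampleCode(p), size = pk$size)
  }))
  if (is.null(pool) || !nrow(pool)) {
    return(MarkerMatrix(matrix(integer(), 0, length(samples),
                               dimnames = list(NULL, samples)),
                        bins = data.frame(region = character(),
                                          center = numeric(),
                                          minSize = numeric(),
                                          maxSize = numeric())))
  }
  pool <- pool[order(pool$size), , drop = FALSE]
  cl <- .gapCluster(pool$size, gapTolBp)
  groups <- split(pool, cl)

  bins <- do.call(rbind, lapply(groups, function(g) {
    data.frame(region = region, center = mean(g$size),
               minSize = min(g$size), maxSize = max(g$size))
  }))
  rownames(bins) <- NULL
  wide <- bins$maxSize - bins$minSize > 2 * gapTolBp
  if (any(wide))
    warning(sum(wide), " bin(s) span more than 2x the gap tolerance ",
            "(single-linkage chaining): centers ",
            paste(round(bins$center[wide], 1), collapse = ", "))

  m <- matrix(0L, nrow(bins), length(samples),
              dimnames = list(NULL, samples))
  collisions <- character()
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    if (anyDuplicated(g$sample))
      collisions <- c(collisions, paste0(
        unique(g$sample[duplicated(g$sample)]), "@",
        round(bins$center[k], 1)))
    m[k, unique(g$sample)] <- 1L
  }
  if (length(collisions))
    warning("sample(s) with >1 peak collapsed inside one bin: ",
            paste(collisions, collapse = ", "))
  MarkerMatrix(m, bins = bins)
}

#' Combine the marker matrices of the two intron regions
#'
#' Column-wise (by marker) concatenation of the first- and second-region
#' matrices; markers keep their region tags, so the combined marker count is
#' the sum of the two. Samples present in only one region are by default
#' dropped from the combined analysis (reported via a warning); with
#' \code{missing = "na"} they are kept and their other-region cells are set
#' to \code{NA}.
#'
#' @param m1,m2 [MarkerMatrix-class] of the first and second region.
#' @param missing how to treat samples present in one region only:
#'   \code{"drop"} (default) or \code{"na"}.
#' @return the combined [MarkerMatrix-class]; sample order follows
#'   \code{m1}.
#' @export
combineRegions <- function(m1, m2, missing = c("drop", "na")) {
  stopifnot(is(m1, "MarkerMatrix"), is(m2, "MarkerMatrix"))
  missing <- match.arg(missing)
  s1 <- sampleCodes(m1); s2 <- sampleCodes(m2)
  common <- intersect(s1, s2)
  if (!length(common))
    stop("the two regions share no samples; refusing a silent union ",
         "(region 1: ", paste(utils::head(s1, 5), collapse = ", "),
         "; region 2: ", paste(utils::head(s2, 5), collapse = ", "), ")")
  only <- c(setdiff(s1, s2), setdiff(s2, s1))
  if (length(only))
    warning("sample(s) present in one region only (",
            paste(only, collapse = ", "), "): ",
            if (missing == "drop") "dropped from the combined matrix"
            else "kept with NA cells for the missing region")

  samples <- if (missing == "drop") s1[s1 %in% common]
             else union(s1, s2)
  cell <- function(m, smp) {
    out <- matrix(NA_integer_, nrow(m), length(smp),
                  dimnames = list(rownames(m), smp))
    have <- intersect(smp, sampleCodes(m))
    out[, have] <- presence(m)[, have, drop = FALSE]
    out
  }
  MarkerMatrix(rbind(cell(m1, samples), cell(m2, samples)),
               bins = rbind(markerBins(m1), markerBins(m2)))
}

#' Per-sample peak counts by region
#'
#' Counts markers present per sample for each intron region individually and
#' their sum -- the per-accession totals reported for TBP panels.
#'
#' @param x a [MarkerMatrix-class] (one region or combined) or a list of
#'   [ConsensusProfile-class].
#' @return data.frame with one row per sample: \code{Sample}, one column per
#'   region present, and \code{Total}.
#' @export
peakCountSummary <- function(x) {
  if (is.list(x) && all(vapply(x, is, logical(1), "ConsensusProfile"))) {
    df <- do.call(rbind, lapply(x, function(p)
      data.frame(Sample = sampleCode(p), region = intronRegion(p),
                 n = nrow(profilePeaks(p)))))
    tab <- tapply(df$n, list(df$Sample, df$region), sum, default = 0L)
  } else {
    stopifnot(is(x, "MarkerMatrix"))
    p <- presence(x)
    region <- markerBins(x)$region
    regs <- unique(region)
    tab <- matrix(0, ncol(p), length(regs),
                  dimnames = list(colnames(p), regs))
    for (r in regs)
      tab[, r] <- colSums(p[region == r, , drop = FALSE], na.rm = TRUE)
  }
  out <- data.frame(Sample = rownames(tab), as.data.frame(tab),
                    check.names = FALSE)
  out$Total <- rowSums(tab)
  rownames(out) <- NULL
  out
}

#' Count polymorphic markers
#'
#' A marker is polymorphic when it is present in at least one sample and
#' absent in at least one (NA cells are ignored).
#'
#' @param m a [MarkerMatrix-class] (or binary markers-x-samples matrix) with
#'   >= 2 samples.
#' @return list with \code{nMarkers}, \code{nPolymorphic},
#'   \code{percentPolymorphic}.
#' @export
polymorphicCount <- function(m) {
  p <- if (is(m, "MarkerMatrix")) presence(m) else as.matrix(m)
  if (ncol(p) < 2L)
    stop("polymorphism is undefined for a single-sample matrix")
  pres <- rowSums(p == 1L, na.rm = TRUE)
  abs_ <- rowSums(p == 0L, na.rm = TRUE)
  poly <- pres >= 1L & abs_ >= 1L
  list(nMarkers = nrow(p), nPolymorphic = sum(poly),
       percentPolymorphic = if (nrow(p)) 100 * sum(poly) / nrow(p) else NA_real_)
}
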