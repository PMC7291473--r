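#' Run the full CE-TBP analysis pipeline
#'
#' From a raw peak table to the analysis report: RFU filtering of every run,
#' consolidation of the four replicates per sample/region, ascending-size
#' marker binning per region, region combination, per-sample peak counts,
#' polymorphic-marker counts, Whittaker dissimilarities, Shannon diversity,
#' intra/inter-specific partition with barcoding-gap overlap, covariance
#' PCA, neighbor-joining tree with bootstrap support, cophenetic fit, and
#' the Mantel correlation between the two intron regions' distance
#' matrices.
#'
#' @param peaks peak table: a file path, a data.frame in dialect columns,
#'   or a list of [CERun-class].
#' @param metadata data.frame with \code{SampleCode}, \code{Species} (or a
#'   CSV path); optional, but required for the gap analysis.
#' @param dialect a [peakDialect()].
#' @param minRfu,maxRfu RFU thresholds (defaults 50, 32000).
#' @param consolidateTolBp replicate-consolidation tolerance (default 1.0).
#' @param minSupport minimum supporting runs per consensus peak (default 2).
#' @param gapTolBp marker-binning gap tolerance (default 1.0).
#' @param bootstrapReps bootstrap replicates for the tree (default 1000).
#' @param nPermutations Mantel permutations (default 999).
#' @param seed integer seed driving bootstrap and permutations.
#' @return list of class \code{"tbpReport"}; see the elements it prints.
#' @export
runTbpPipeline <- function(peaks, metadata = NULL, dialect = peakDialect(),
                           minRfu = 50, maxRfu = 32000,
                           consolidateTolBp = 1.0, minSupport = 2,
                           gapTolBp = 1.0, bootstrapReps = 1000,
                           nPermutations = 999, seed = NULL) {
  runs <- if (is.list(peaks) && length(peaks) &&
              all(vapply(peaks, is, logical(1), "CERun"))) peaks
          else readPeakTable(peaks, dialect)
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- readSampleMetadata(metadata)

  runs <- lapply(runs, filterRun, minRfu = minRfu, maxRfu = maxRfu)
  exclusions <- Filter(isExcluded, runs)

  key <- vapply(runs, function(r)
    paste(r@sampleCode, r@intronRegion, sep = "\r"), character(1))
  profiles <- lapply(split(runs, key), consolidateRuns,
                     sizeTolBp = consolidateTolBp, minSupport = minSupport)
  noData <- Filter(function(p) p@status == "no_data", profiles)
  profiles <- Filter(function(p) p@status == "ok", profiles)

  regions <- unique(vapply(profiles, intronRegion, character(1)))
  matrices <- lapply(stats::setNames(nm = regions), function(rg)
    binMarkers(Filter(function(p) intronRegion(p) == rg, profiles),
               gapTolBp = gapTolBp))
  combined <- if (length(regions) == 2L)
    combineRegions(matrices$first, matrices$second) else matrices[[1]]

  counts <- peakCountSummary(combined)
  poly <- polymorphicCount(combined)
  d <- whittakerDist(combined)
  shannon <- shannonIndex(combined, "presence-frequency")

  gap <- NULL
  if (!is.null(metadata)) {
    checkSampleCodes(sampleCodes(combined), metadata)
    gap <- partitionIntraInter(d, metadata)
  }

  pca <- pcaCovariance(combined)
  tree <- bootstrapSupport(combined, nReps = bootstrapReps, seed = seed)
  coph <- copheneticCorrelation(tree, d)

  mantel <- NULL
  if (length(regions) == 2L) {
    d1 <- whittakerDist(matrices$first)
    d2 <- whittakerDist(matrices$second)
    mantel <- matrixCorrelation(d1, d2, nPermutations = nPermutations,
                                seed = seed)
  }

  structure(list(runs = runs, exclusions = exclusions, noData = noData,
                 profiles = profiles, matrices = matrices,
                 combined = combined, counts = counts, polymorphic = poly,
                 dist = d, shannon = shannon, gap = gap, pca = pca,
                 tree = tree, cophenetic = coph, mantel = mantel,
                 params = list(minRfu = minRfu, maxRfu = maxRfu,
                               consolidateTolBp = consolidateTolBp,
                               minSupport = minSupport,
                               gapTolBp = gapTolBp,
                               bootstrapReps = bootstrapReps,
                               nPermutations = nPermutations,
                               seed = seed)),
            class = "tbpReport")
}

#' @export
print.tbpReport <- function(x, ...) {
  cat("CE-TBP pipeline report\n")
  cat("  runs:", length(x$runs), "(", length(x$exclusions), "excluded )\n")
  cat("  samples:", ncol(x$combined), " markers:", nrow(x$combined), "\n")
  cat(sprintf("  polymorphic markers: %d / %d (%.1f%%)\n",
              x$polymorphic$nPolymorphic, x$polymorphic$nMarkers,
              x$polymorphic$percentPolymorphic))
  cat(sprintf("  Shannon index (presence-frequency): %.3f\n", x$shannon))
  if (!is.null(x$gap)) print(x$gap)
  if (!x$pca$degenerate)
    cat(sprintf("  PCA: PC1 %.2f%%, PC2 %.2f%% of total variance\n",
                x$pca$percentVar[1], x$pca$percentVar[2]))
  cat(sprintf("  cophenetic correlation: r = %.3f\n", x$cophenetic$r))
  if (!is.null(x$mantel))
    cat(sprintf("  between-region Mantel: r = %.3f, p = %.4g\n",
                x$mantel$r, x$mantel$p))
  invisible(x)
}

#' Summarize a report as a flat named list (JSON-friendly)
#'
#' @param x a \code{tbpReport}.
#' @return named list of the report's headline numbers.
#' @export
reportSummary <- function(x) {
  stopifnot(inherits(x, "tbpReport"))
  out <- list(
    n_samples = ncol(x$combined),
    n_markers = nrow(x$combined),
    n_polymorphic = x$polymorphic$nPolymorphic,
    percent_polymorphic = x$polymorphic$percentPolymorphic,
    shannon = x$shannon,
    pc1_percent = if (!x$pca$degenerate) x$pca$percentVar[1] else 0,
    pc2_percent = if (!x$pca$degenerate) x$pca$percentVar[2] else 0,
    cophenetic_r = x$cophenetic$r)
  if (!is.null(x$gap)) {
    out$intra_min <- x$gap$intraRange[1]
    out$intra_max <- x$gap$intraRange[2]
    out$inter_min <- x$gap$interRange[1]
    out$inter_max <- x$gap$interRange[2]
    out$overlap_percent <- x$gap$overlapPercent
  }
  if (!is.null(x$mantel)) {
    out$mantel_r <- x$mantel$r
    out$mantel_p <- x$mantel$p
  }
  out
}
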