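#' Apply the RFU height thresholds to a run
#'
#' Only peaks whose height exceeds \code{minRfu} are recorded (strictly
#' greater: a peak at exactly the threshold is removed), while any peak above
#' \code{maxRfu} is out of scale and excludes the entire run from analysis.
#' Defaults are the 50 / 32,000 RFU working thresholds of the CE detector.
#'
#' Filtering is idempotent: applying it twice changes nothing.
#'
#' @param run a [CERun-class].
#' @param minRfu lower recording threshold (RFU), default 50.
#' @param maxRfu out-of-scale threshold (RFU), default 32000.
#' @return the filtered [CERun-class]; if any peak exceeded \code{maxRfu}
#'   the run comes back with \code{excluded = TRUE} and reason
#'   \code{"out of scale"}, peaks untouched for inspection.
#' @examples
#' r <- CERun("S1", "first", peaks = data.frame(size = c(100, 200, 300),
#'                                              height = c(49, 50, 51)))
#' runPeaks(filterRun(r))   # only the 51-RFU peak survives
#' @export
filterRun <- function(run, minRfu = 50, maxRfu = 32000) {
  stopifnot(is(run, "CERun"))
  if (!(minRfu > 0 && maxRfu > 0 && minRfu < maxRfu))
    stop("thresholds must be positive with minRfu < maxRfu")
  if (run@excluded) return(run)
  p <- runPeaks(run)
  if (nrow(p) && any(p$height > maxRfu)) {
    run@excluded <- TRUE
    run@exclusionReason <- "out of scale"
    return(run)
  }
  run@peaks <- p[p$height > minRfu, , drop = FALSE]
  rownames(run@peaks) <- NULL
  run
}

#' Consolidate the replicate runs of one sample/region
#'
#' The four CE runs of a sample (2 independent amplifications x 2 dilutions)
#' are merged into one [ConsensusProfile-class]. Peaks are pooled across the
#' surviving (non-excluded) runs, sorted, and clustered by single linkage: a
#' gap larger than \code{sizeTolBp} between consecutive sizes starts a new
#' cluster. A cluster becomes a consensus peak only if it contains peaks from
#' at least \code{minSupport} distinct runs \emph{and} -- when both
#' amplifications still have surviving runs -- from both amplifications, the
#' reproducibility the replicate design exists to enforce. The consensus size
#' is the mean of the member sizes.
#'
#' @param runs list of [CERun-class] sharing sample code and region (the
#'   <= 4 filtered replicates).
#' @param sizeTolBp within-sample clustering tolerance (bp), default 1.0.
#' @param minSupport minimum number of distinct supporting runs, default 2.
#' @return a [ConsensusProfile-class]; status \code{"no_data"} when no run
#'   survived.
#' @export
consolidateRuns <- function(runs, sizeTolBp = 1.0, minSupport = 2) {
  stopifnot(length(runs) >= 1L, all(vapply(runs, is, logical(1), "CERun")))
  sc <- unique(vapply(runs, function(r) r@sampleCode, character(1)))
  rg <- unique(vapply(runs, function(r) r@intronRegion, character(1)))
  if (length(sc) != 1L || length(rg) != 1L)
    stop("all runs must share one sample code and one intron region")
  alive <- Filter(function(r) !r@excluded, runs)
  if (length(alive) < length(runs))
    warning(sampleCode(runs[[1]]), "/", rg, ": ",
            length(runs) - length(alive),
            " excluded run(s); proceeding with the remaining ",
            length(alive))
  if (!length(alive))
    return(ConsensusProfile(sc, rg, status = "no_data"))

  amps <- unique(vapply(alive, function(r) r@amplificationId, character(1)))
  pool <- do.call(rbind, lapply(seq_along(alive), function(i) {
    p <- runPeaks(alive[[i]])
    if (!nrow(p)) return(NULL)
    data.frame(size = p$size, height = p$height, run = i,
               amp = alive[[i]]@amplificationId)
  }))
  if (is.null(pool) || !nrow(pool))
    return(ConsensusProfile(sc, rg))

  pool <- pool[order(pool$size), , drop = FALSE]
  cl <- cumsum(c(1, diff(pool$size) > sizeTolBp))
  keep <- lapply(split(pool, cl), function(g) {
    okSupport <- length(unique(g$run)) >= minSupport
    okAmps <- length(amps) < 2L || length(unique(g$amp)) == 2L
    if (okSupport && okAmps) {
      data.frame(size = mean(g$size),
                 support = length(unique(g$run)),
                 meanHeight = mean(g$height))
    } else NULL
  })
  peaks <- do.call(rbind, keep)
  if (is.null(peaks)) ConsensusProfile(sc, rg) else
    ConsensusProfile(sc, rg, peaks = peaks)
}
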