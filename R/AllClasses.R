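#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.REGIONS <- c("first", "second")

#' Normalize an intron-region token
#'
#' CE-TBP data name the two amplified beta-tubulin intron regions in several
#' ways (numeric, ordinal, or by the touchdown cycle name of the primer pair).
#' All accepted tokens are mapped to the canonical labels \code{"first"} and
#' \code{"second"}.
#'
#' @param x character vector of region tokens. Accepted (case-insensitive):
#'   \code{"1"}, \code{"first"}, \code{"TBPTD1i"} for the first intron region;
#'   \code{"2"}, \code{"second"}, \code{"TBPTD2i"} for the second.
#' @return character vector of canonical region labels.
#' @examples
#' normalizeRegion(c("1", "TBPTD2i", "first"))
#' @export
normalizeRegion <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x0))
  out[x0 %in% c("1", "first", "tbptd1i", "intron1", "i")] <- "first"
  out[x0 %in% c("2", "second", "tbptd2i", "intron2", "ii")] <- "second"
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unrecognized intron-region token(s): ", paste(bad, collapse = ", "))
  }
  out
}

.validPeaks <- function(peaks) {
  need <- c("size", "height")
  if (!is.data.frame(peaks)) return("'peaks' must be a data.frame")
  if (!all(need %in% names(peaks)))
    return(paste0("'peaks' must have columns ", paste(need, collapse = ", ")))
  if (nrow(peaks)) {
    if (any(!is.finite(peaks$size)) || any(peaks$size <= 0))
      return("peak sizes must be finite and > 0")
    if (any(!is.finite(peaks$height)) || any(peaks$height < 0))
      return("peak heights must be finite and >= 0")
    if (is.unsorted(peaks$size))
      return("peaks must be sorted ascending by size")
    if ("area" %in% names(peaks) && any(peaks$area < 0, na.rm = TRUE))
      return("peak areas must be >= 0")
  }
  TRUE
}

#' CERun: one capillary-electrophoresis run of one sample
#'
#' A \code{CERun} holds the called peaks of a single CE injection of one
#' sample, one intron region, one of the two independent amplifications and
#' one of the two dilutions (the four-run replicate scheme). Peaks are stored
#' as a data.frame with fractional \code{size} (bp) and \code{height} (RFU),
#' optionally \code{area} and \code{dye}, always sorted ascending by size.
#'
#' @slot sampleCode accession identifier.
#' @slot intronRegion \code{"first"} or \code{"second"}.
#' @slot amplificationId identifier of the independent amplification.
#' @slot dilutionId identifier of the dilution.
#' @slot peaks data.frame of called peaks (size, height, area, dye).
#' @slot standardOk logical; did the run pass size-standard QC.
#' @slot excluded logical; whole-run exclusion (e.g. out-of-scale peak).
#' @slot exclusionReason character; why the run was excluded ("" if not).
#' @exportClass CERun
setClass("CERun",
  representation(
    sampleCode = "character",
    intronRegion = "character",
    amplificationId = "character",
    dilutionId = "character",
    peaks = "data.frame",
    standardOk = "logical",
    excluded = "logical",
    exclusionReason = "character"
  ),
  validity = function(object) {
    msgs <- character()
    for (s in c("sampleCode", "intronRegion", "amplificationId",
                "dilutionId", "exclusionReason"))
      if (length(slot(object, s)) != 1L)
        msgs <- c(msgs, paste0("'", s, "' must be length 1"))
    if (length(object@intronRegion) == 1L &&
        !object@intronRegion %in% .REGIONS)
      msgs <- c(msgs, "intronRegion must be 'first' or 'second'")
    v <- .validPeaks(object@peaks)
    if (!isTRUE(v)) msgs <- c(msgs, v)
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a CERun
#'
#' @param sampleCode,intronRegion,amplificationId,dilutionId run identity;
#'   the region token is normalized with [normalizeRegion()].
#' @param peaks data.frame with numeric columns \code{size} (bp, > 0) and
#'   \code{height} (RFU, >= 0); optional \code{area}, \code{dye}. Rows are
#'   sorted ascending by size.
#' @param standardOk logical size-standard QC flag.
#' @return a [CERun-class] object.
#' @examples
#' CERun("S1", "1", "A", "D1",
#'       data.frame(size = c(450, 302.1), height = c(900, 1200)))
#' @export
CERun <- function(sampleCode, intronRegion, amplificationId = "A1",
                  dilutionId = "D1",
                  peaks = data.frame(size = numeric(), height = numeric()),
                  standardOk = TRUE) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks)) peaks <- peaks[order(peaks$size), , drop = FALSE]
  rownames(peaks) <- NULL
  new("CERun",
      sampleCode = as.character(sampleCode),
      intronRegion = normalizeRegion(intronRegion),
      amplificationId = as.character(amplificationId),
      dilutionId = as.character(dilutionId),
      peaks = peaks, standardOk = isTRUE(standardOk),
      excluded = FALSE, exclusionReason = "")
}

setMethod("show", "CERun", function(object) {
  cat("CERun:", object@sampleCode,
      sprintf("[%s intron, amp %s, dil %s]", object@intronRegion,
              object@amplificationId, object@dilutionId),
      "-", nrow(object@peaks), "peaks")
  if (object@excluded) cat(" [EXCLUDED:", object@exclusionReason, "]")
  if (!object@standardOk) cat(" [standard FAILED]")
  cat("\n")
})

#' @describeIn CERun peak table accessor (data.frame, ascending size)
#' @param x a CERun
#' @export
runPeaks <- function(x) {
  stopifnot(is(x, "CERun"))
  x@peaks
}

#' @describeIn CERun run identity accessors
#' @export
sampleCode <- function(x) {
  if (is(x, "CERun") || is(x, "ConsensusProfile")) return(x@sampleCode)
  stop("no sampleCode for class ", class(x))
}

#' @describeIn CERun intron-region accessor
#' @export
intronRegion <- function(x) {
  if (is(x, "CERun") || is(x, "ConsensusProfile")) return(x@intronRegion)
  stop("no intronRegion for class ", class(x))
}

#' @describeIn CERun whole-run exclusion flag
#' @export
isExcluded <- function(x) {
  stopifnot(is(x, "CERun"))
  x@excluded
}

#' ConsensusProfile: the replicate-consolidated peak list of one sample
#'
#' The four CE runs of a sample/region (2 amplifications x 2 dilutions) are
#' consolidated into one consensus peak list. Each consensus peak records how
#' many distinct runs supported it and the mean height across those runs.
#'
#' @slot sampleCode accession identifier.
#' @slot intronRegion \code{"first"} or \code{"second"}.
#' @slot peaks data.frame with columns \code{size} (mean bp, strictly
#'   ascending), \code{support} (1--4 contributing runs), \code{meanHeight}.
#' @slot status \code{"ok"} or \code{"no_data"} (all runs excluded).
#' @exportClass ConsensusProfile
setClass("ConsensusProfile",
  representation(
    sampleCode = "character",
    intronRegion = "character",
    peaks = "data.frame",
    status = "character"
  ),
  validity = function(object) {
    msgs <- character()
    need <- c("size", "support", "meanHeight")
    if (!all(need %in% names(object@peaks)))
      msgs <- c(msgs, paste0("peaks must have columns ",
                             paste(need, collapse = ", ")))
    else if (nrow(object@peaks)) {
      if (any(diff(object@peaks$size) <= 0))
        msgs <- c(msgs, "consensus sizes must be strictly ascending")
      if (any(object@peaks$support < 1))
        msgs <- c(msgs, "support must be >= 1")
    }
    if (!object@status %in% c("ok", "no_data"))
      msgs <- c(msgs, "status must be 'ok' or 'no_data'")
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a ConsensusProfile
#'
#' @param sampleCode,intronRegion profile identity.
#' @param peaks data.frame with \code{size}, \code{support},
#'   \code{meanHeight}; sorted by size.
#' @param status \code{"ok"} or \code{"no_data"}.
#' @return a [ConsensusProfile-class].
#' @export
ConsensusProfile <- function(sampleCode, intronRegion,
                             peaks = data.frame(size = numeric(),
                                                support = integer(),
                                                meanHeight = numeric()),
                             status = "ok") {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks)) peaks <- peaks[order(peaks$size), , drop = FALSE]
  rownames(peaks) <- NULL
  new("ConsensusProfile", sampleCode = as.character(sampleCode),
      intronRegion = normalizeRegion(intronRegion), peaks = peaks,
      status = status)
}

setMethod("show", "ConsensusProfile", function(object) {
  cat("ConsensusProfile:", object@sampleCode,
      sprintf("[%s intron]", object@intronRegion), "-",
      nrow(object@peaks), "consensus peaks")
  if (object@status == "no_data") cat(" [NO DATA]")
  cat("\n")
})

#' @describeIn ConsensusProfile consensus peak table accessor
#' @param x a ConsensusProfile
#' @export
profilePeaks <- function(x) {
  stopifnot(is(x, "ConsensusProfile"))
  x@peaks
}

#' MarkerMatrix: the binary presence/absence marker matrix
#'
#' The central container of a CE-TBP experiment: binned amplicon sizes
#' (markers, rows) by samples (columns), with cells 1 for presence and 0 for
#' absence (NA for a sample missing a whole region after
#' [combineRegions()]). Extends
#' \linkS4class{SummarizedExperiment}: bin descriptions (region, center and
#' extent in bp) live in \code{rowData}, sample metadata in \code{colData},
#' and the binary cells in the single assay \code{"presence"}.
#'
#' @seealso [binMarkers()], [combineRegions()], [whittakerDist()]
#' @exportClass MarkerMatrix
setClass("MarkerMatrix", contains = "SummarizedExperiment",
  validity = function(object) {
    msgs <- character()
    if (!"presence" %in% SummarizedExperiment::assayNames(object))
      return("assay 'presence' is required")
    a <- SummarizedExperiment::assay(object, "presence")
    if (!all(a %in% c(0, 1, NA)))
      msgs <- c(msgs, "presence cells must be 0, 1 or NA")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("region", "center", "minSize", "maxSize")
    if (!all(need %in% colnames(rd)))
      msgs <- c(msgs, paste0("rowData must have columns ",
                             paste(need, collapse = ", ")))
    else {
      if (!all(rd$region %in% .REGIONS))
        msgs <- c(msgs, "bin regions must be 'first' or 'second'")
      for (r in unique(rd$region)) {
        i <- rd$region == r
        if (sum(i) > 1L) {
          o <- order(rd$center[i])
          mn <- rd$minSize[i][o]; mx <- rd$maxSize[i][o]
          if (any(mx[-length(mx)] >= mn[-1]))
            msgs <- c(msgs, paste0("bins of region '", r, "' overlap"))
        }
      }
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a MarkerMatrix
#'
#' @param presence numeric/integer matrix of 0/1 (markers x samples); column
#'   names are sample codes.
#' @param bins data.frame or DataFrame with one row per marker: columns
#'   \code{region}, \code{center}, \code{minSize}, \code{maxSize}.
#' @param sampleData optional data.frame of per-sample metadata (rows match
#'   the presence columns).
#' @return a [MarkerMatrix-class].
#' @examples
#' m <- MarkerMatrix(matrix(c(1, 0, 1, 1), 2,
#'                          dimnames = list(NULL, c("A", "B"))),
#'                   bins = data.frame(region = "first",
#'                                     center = c(302.4, 450),
#'                                     minSize = c(302.1, 450),
#'                                     maxSize = c(302.8, 450)))
#' presence(m)
#' @export
MarkerMatrix <- function(presence, bins, sampleData = NULL) {
  presence <- as.matrix(presence)
  mode(presence) <- "integer"
  bins <- DataFrame(as.data.frame(bins))
  if (is.null(rownames(presence)) && nrow(presence))
    rownames(presence) <- paste0(substr(bins$region, 1, 1), ":",
                                 format(bins$center, trim = TRUE))
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(presence))
  } else {
    DataFrame(as.data.frame(sampleData), row.names = colnames(presence))
  }
  se <- SummarizedExperiment(assays = list(presence = presence),
                             rowData = bins, colData = cd)
  new("MarkerMatrix", se)
}

setMethod("show", "MarkerMatrix", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("MarkerMatrix:", nrow(object), "markers x", ncol(object), "samples\n")
  for (r in .REGIONS) {
    n <- sum(rd$region == r)
    if (n) cat("  ", r, "intron region:", n, "markers\n")
  }
  cat("  samples:", paste(utils::head(colnames(object), 6), collapse = ", "),
      if (ncol(object) > 6) "..." else "", "\n")
})

#' @describeIn MarkerMatrix the binary cells (markers x samples)
#' @param x a MarkerMatrix
#' @export
presence <- function(x) {
  stopifnot(is(x, "MarkerMatrix"))
  SummarizedExperiment::assay(x, "presence")
}

#' @describeIn MarkerMatrix bin descriptions (region, center, extent in bp)
#' @export
markerBins <- function(x) {
  stopifnot(is(x, "MarkerMatrix"))
  as.data.frame(SummarizedExperiment::rowData(x))
}

#' @describeIn MarkerMatrix sample codes (column names)
#' @export
sampleCodes <- function(x) {
  stopifnot(is(x, "MarkerMatrix"))
  colnames(x)
}

# samples-as-rows binary matrix used by the diversity/ordination layer
.sampleRows <- function(x) {
  if (is(x, "MarkerMatrix")) t(presence(x)) else as.matrix(x)
}
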