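#' Peak-table dialect
#'
#' Fragment-analysis software (GeneMapper and friends) exports peak tables
#' with locale- and template-dependent column names. A dialect maps the
#' columns this package needs onto the header names of a concrete export.
#' \code{sample}, \code{size} and \code{height} are required; the rest are
#' optional and default to single-run placeholders when absent.
#'
#' @param sample,region,amplification,dilution,dye,size,height,area header
#'   names in the file.
#' @param sep field separator; \code{dec} decimal mark.
#' @return a list of class \code{"tbpDialect"}.
#' @examples
#' peakDialect(size = "Size (bp)", height = "Hgt", sep = "\t")
#' @export
peakDialect <- function(sample = "Sample", region = "Region",
                        amplification = "Amp", dilution = "Dilution",
                        dye = "Dye", size = "Size", height = "Height",
                        area = "Area", sep = ",", dec = ".") {
  structure(list(sample = sample, region = region,
                 amplification = amplification, dilution = dilution,
                 dye = dye, size = size, height = height, area = area,
                 sep = sep, dec = dec),
            class = "tbpDialect")
}

.dialectCol <- function(df, dialect, what, required = FALSE,
                        default = NULL) {
  nm <- dialect[[what]]
  if (nm %in% names(df)) return(df[[nm]])
  if (required)
    stop("peak table is missing required column '", nm, "' (", what, ")")
  if (is.null(default)) NULL else rep(default, nrow(df))
}

# shared by readPeakTable() and simulateCeRuns(): a peak-table data.frame
# (already in dialect columns) -> list of CERun
.tableToRuns <- function(df, dialect) {
  sample <- as.character(.dialectCol(df, dialect, "sample", required = TRUE))
  size <- suppressWarnings(as.numeric(
    .dialectCol(df, dialect, "size", required = TRUE)))
  height <- suppressWarnings(as.numeric(
    .dialectCol(df, dialect, "height", required = TRUE)))
  region <- .dialectCol(df, dialect, "region", default = "first")
  amp <- as.character(.dialectCol(df, dialect, "amplification",
                                  default = "A1"))
  dil <- as.character(.dialectCol(df, dialect, "dilution", default = "D1"))
  dye <- .dialectCol(df, dialect, "dye")
  area <- .dialectCol(df, dialect, "area")
  if (!is.null(area)) area <- suppressWarnings(as.numeric(area))

  bad <- !is.finite(size) | !is.finite(height) | size <= 0 | height < 0
  badRows <- which(bad)
  if (length(badRows))
    warning(length(badRows), " row(s) with unparseable/invalid size or ",
            "height skipped (rows ", paste(utils::head(badRows, 10),
            collapse = ", "), if (length(badRows) > 10) ", ..." else "", ")")
  keep <- !bad
  region <- normalizeRegion(region[keep])
  tab <- data.frame(sample = sample[keep], region = region,
                    amp = amp[keep], dil = dil[keep],
                    size = size[keep], height = height[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(area)) tab$area <- area[keep]
  if (!is.null(dye)) tab$dye <- as.character(dye)[keep]

  # duplicate (sample, region, amp, dil, size) rows: keep highest RFU
  key <- paste(tab$sample, tab$region, tab$amp, tab$dil, tab$size, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate peak row(s): keeping the ",
            "highest-RFU row of each duplicate set")
    tab <- tab[order(key, -tab$height), , drop = FALSE]
    tab <- tab[!duplicated(paste(tab$sample, tab$region, tab$amp, tab$dil,
                                 tab$size, sep = "\r")), , drop = FALSE]
  }

  runKey <- paste(tab$sample, tab$region, tab$amp, tab$dil, sep = "\r")
  runs <- lapply(split(seq_len(nrow(tab)), runKey), function(i) {
    p <- tab[i, , drop = FALSE]
    cols <- intersect(c("size", "height", "area", "dye"), names(p))
    CERun(p$sample[1], p$region[1], p$amp[1], p$dil[1],
          peaks = p[order(p$size), cols, drop = FALSE])
  })
  runs <- unname(runs)
  attr(runs, "badRows") <- badRows
  runs
}

#' Read a CE peak table into CERun objects
#'
#' Ingests a delimited peak table (one row per called peak) and splits it
#' into one [CERun-class] per (sample, region, amplification, dilution)
#' combination found. Peaks come out sorted ascending by size; sizes stay
#' fractional, never rounded. Rows whose size or height cannot be parsed are
#' reported via a warning and listed in the \code{"badRows"} attribute of the
#' result, not silently dropped. Duplicated (sample, region, amplification,
#' dilution, size) rows keep the highest-RFU record with a warning.
#'
#' @param path file path of the delimited table (or a data.frame already in
#'   dialect columns).
#' @param dialect a [peakDialect()] mapping required columns.
#' @return list of [CERun-class]; attribute \code{"badRows"} holds the row
#'   numbers that failed to parse.
#' @export
readPeakTable <- function(path, dialect = peakDialect()) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, header = TRUE, sep = dialect$sep,
                      dec = dialect$dec, stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = "")
  }
  .tableToRuns(df, dialect)
}

#' Write CERun objects back to a peak table
#'
#' Inverse of [readPeakTable()]: full-precision sizes/heights so that a
#' write/read round trip reproduces the runs exactly.
#'
#' @param runs list of [CERun-class].
#' @param path output file path.
#' @param dialect a [peakDialect()].
#' @return invisibly, the data.frame written.
#' @export
writePeakTable <- function(runs, path, dialect = peakDialect()) {
  rows <- lapply(runs, function(r) {
    p <- runPeaks(r)
    if (!nrow(p)) return(NULL)
    out <- data.frame(a = r@sampleCode, b = r@intronRegion,
                      c = r@amplificationId, d = r@dilutionId,
                      e = if ("dye" %in% names(p)) p$dye else "FAM",
                      f = p$size, g = p$height,
                      h = if ("area" %in% names(p)) p$area else NA_real_)
    names(out) <- unlist(dialect[c("sample", "region", "amplification",
                                   "dilution", "dye", "size", "height",
                                   "area")])
    out
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame()
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = dialect$sep, dec = dialect$dec,
                     row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Size-standard definition
#'
#' The expected fragment lengths of the co-injected sizing ladder, used to
#' validate that a run was sized against a correctly assigned standard.
#'
#' @param name ladder name.
#' @param sizes strictly ascending expected fragment lengths (bp); at least
#'   two.
#' @return list of class \code{"sizeStandard"}.
#' @examples
#' sizeStandard("demo", c(100, 200, 300, 400))
#' @export
sizeStandard <- function(name, sizes) {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 2L) stop("a size standard needs at least 2 fragments")
  if (any(diff(sizes) <= 0)) stop("standard fragment sizes must be strictly ascending")
  structure(list(name = name, sizes = sizes), class = "sizeStandard")
}

#' A representative long-read sizing ladder
#'
#' A generic 24-fragment ladder spanning 20--1200 bp, shaped like the
#' long-fragment standards used for CE-TBP sizing. It is a representative
#' stand-in for QC demonstrations and tests, not a vendor fragment list.
#'
#' @return a [sizeStandard()] definition.
#' @export
defaultLadder <- function() {
  sizeStandard("representative-1200",
               c(20, 40, 60, 80, 100, 114, 140, 160, 200, 250, 300, 340,
                 400, 450, 500, 550, 600, 700, 800, 900, 1000, 1100, 1160,
                 1200))
}

#' Validate observed size-standard peaks against the expected ladder
#'
#' Each expected ladder fragment is matched to at most one observed standard
#' peak within \code{sizeTolBp} (closest pairs first); observed peaks whose
#' height falls below \code{relHeightMin} of the tallest observed standard
#' peak are not eligible. A sample peak is sizeable only when both the
#' preceding and the subsequent ladder fragments matched. The run passes only
#' if every expected fragment inside the sample's size range matched; fewer
#' than two matches anywhere fails the run outright.
#'
#' @param observed data.frame of observed standard peaks (\code{size},
#'   \code{height}), sorted ascending by size.
#' @param standard a [sizeStandard()].
#' @param relHeightMin minimum observed height relative to the tallest
#'   observed standard peak for a peak to count (default 0.1).
#' @param sizeTolBp matching tolerance in bp (default 0.5).
#' @param sampleRange optional numeric(2): the size range spanned by the
#'   sample's own peaks; defaults to the full ladder span.
#' @return list with \code{fragments} (data.frame: expected, matched,
#'   observedSize, delta), \code{pass}, \code{nMatched}, and
#'   \code{sizeable(sizes)}, a function reporting which sample peak sizes
#'   are flanked by matched fragments.
#' @export
validateSizeStandard <- function(observed, standard, relHeightMin = 0.1,
                                 sizeTolBp = 0.5, sampleRange = NULL) {
  stopifnot(inherits(standard, "sizeStandard"))
  observed <- as.data.frame(observed)
  if (nrow(observed) && is.unsorted(observed$size))
    stop("observed standard peaks must be sorted ascending by size")
  exp <- standard$sizes
  eligible <- if (nrow(observed)) {
    observed$height >= relHeightMin * max(observed$height)
  } else logical(0)
  obs <- observed$size[eligible]

  matched <- rep(FALSE, length(exp))
  obsSize <- rep(NA_real_, length(exp))
  if (length(obs)) {
    # all candidate pairs within tolerance, closest first; each side used once
    cand <- expand.grid(i = seq_along(exp), j = seq_along(obs))
    cand$delta <- abs(exp[cand$i] - obs[cand$j])
    cand <- cand[cand$delta <= sizeTolBp, , drop = FALSE]
    cand <- cand[order(cand$delta, cand$i, cand$j), , drop = FALSE]
    usedObs <- logical(length(obs))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!matched[i] && !usedObs[j]) {
        matched[i] <- TRUE; usedObs[j] <- TRUE; obsSize[i] <- obs[j]
      }
    }
  }
  if (is.null(sampleRange)) sampleRange <- range(exp)
  inRange <- exp >= sampleRange[1] & exp <= sampleRange[2]
  pass <- sum(matched) >= 2L && all(matched[inRange])

  sizeable <- function(sizes) {
    vapply(sizes, function(s) {
      prev <- which(exp <= s)      # the immediately preceding fragment
      nxt <- which(exp >= s)       # the immediately subsequent fragment
      length(prev) > 0L && length(nxt) > 0L &&
        matched[max(prev)] && matched[min(nxt)]
    }, logical(1))
  }
  list(fragments = data.frame(expected = exp, matched = matched,
                              observedSize = obsSize,
                              delta = abs(exp - obsSize)),
       pass = pass, nMatched = sum(matched), sizeable = sizeable)
}

#' Read sample metadata
#'
#' @param path CSV with at least columns \code{SampleCode} and
#'   \code{Species}; further columns (tribe/section/form/ploidy, free text)
#'   are carried along.
#' @return data.frame with unique \code{SampleCode}.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("SampleCode", "Species")
  if (!all(need %in% names(df)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$SampleCode))
    stop("duplicate sample codes in metadata: ",
         paste(unique(df$SampleCode[duplicated(df$SampleCode)]),
               collapse = ", "))
  df
}

#' Cross-reference sample codes between peak data and metadata
#'
#' @param codes sample codes present in the peak data (or a MarkerMatrix).
#' @param metadata data.frame from [readSampleMetadata()].
#' @return invisibly TRUE; errors listing any peak-data code missing from
#'   the metadata.
#' @export
checkSampleCodes <- function(codes, metadata) {
  if (is(codes, "MarkerMatrix")) codes <- sampleCodes(codes)
  missing <- setdiff(codes, metadata$SampleCode)
  if (length(missing))
    stop("sample code(s) absent from metadata: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Write / read the binary marker matrix as CSV
#'
#' Samples are rows; each column header carries the region tag and the bin
#' center at full precision (\code{first:302.45}), so a write/read round trip
#' reproduces the matrix bit-exactly (bin extents collapse to the center).
#'
#' @param x a [MarkerMatrix-class].
#' @param path output CSV path.
#' @return invisibly \code{path}.
#' @export
writeMarkerMatrix <- function(x, path) {
  stopifnot(is(x, "MarkerMatrix"))
  bins <- markerBins(x)
  hdr <- if (nrow(bins)) paste0(bins$region, ":",
                                sprintf("%.17g", bins$center))
         else character(0)
  m <- t(presence(x))
  colnames(m) <- hdr
  df <- data.frame(Sample = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMarkerMatrix
#' @export
readMarkerMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Sample" %in% names(df)) stop("marker-matrix CSV needs a 'Sample' column")
  samples <- as.character(df$Sample)
  mcols <- setdiff(names(df), "Sample")
  if (!length(mcols)) {
    return(MarkerMatrix(matrix(integer(), 0, length(samples),
                               dimnames = list(NULL, samples)),
                        bins = data.frame(region = character(),
                                          center = numeric(),
                                          minSize = numeric(),
                                          maxSize = numeric())))
  }
  parts <- strsplit(mcols, ":", fixed = TRUE)
  region <- vapply(parts, `[`, character(1), 1)
  center <- as.numeric(vapply(parts, `[`, character(1), 2))
  m <- t(as.matrix(df[, mcols, drop = FALSE]))
  colnames(m) <- samples
  MarkerMatrix(m, bins = data.frame(region = normalizeRegion(region),
                                    center = center, minSize = center,
                                    maxSize = center))
}
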