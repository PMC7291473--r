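# Independent oracles used across the suite. These deliberately take the
# dumb route (enumeration, brute force, closed forms) and never call the
# package code paths they check.

# Whittaker via the a/b/c decomposition, counted with explicit loops
abcWhittaker <- function(x, y) {
  a <- 0; b <- 0; cc <- 0
  for (k in seq_along(x)) {
    if (x[k] == 1 && y[k] == 1) a <- a + 1
    else if (x[k] == 1) b <- b + 1
    else if (y[k] == 1) cc <- cc + 1
  }
  (b + cc) / (2 * a + b + cc)
}

# Whittaker via the S / mean-alpha - 1 route
unionWhittaker <- function(x, y) {
  S <- sum(x | y)
  S / ((sum(x) + sum(y)) / 2) - 1
}

# exhaustive single-linkage clustering with a gap cut, via hclust
oracleGapBins <- function(sizes, gapTol) {
  if (length(sizes) == 1L) return(1L)
  hc <- stats::hclust(stats::dist(sizes), method = "single")
  stats::cutree(hc, h = gapTol)
}

# all concrete expansions of an IUPAC primer (fine for degeneracy <= 96)
expandIUPAC <- function(primer) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[
    strsplit(toupper(as.character(primer)), "")[[1]]], "")
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# brute-force degenerate matching: minimum Hamming distance of any concrete
# expansion against every window (subject N never matches)
bruteSites <- function(subject, primer, maxMismatch) {
  subject <- toupper(as.character(subject))
  exps <- expandIUPAC(primer)
  k <- nchar(exps[1])
  n <- nchar(subject)
  if (k > n) return(integer(0))
  hits <- integer(0)
  for (st in seq_len(n - k + 1)) {
    win <- strsplit(substr(subject, st, st + k - 1), "")[[1]]
    best <- k
    for (e in exps) {
      mm <- sum(strsplit(e, "")[[1]] != win | win == "N")
      if (mm < best) best <- mm
    }
    if (best <= maxMismatch) hits <- c(hits, st)
  }
  hits
}

# random binary marker matrix (samples x markers) with no all-zero rows
randomBinaryRows <- function(nSamples, nMarkers, p = 0.5) {
  repeat {
    m <- matrix(rbinom(nSamples * nMarkers, 1, p), nSamples,
                dimnames = list(paste0("s", seq_len(nSamples)), NULL))
    if (all(rowSums(m) > 0)) return(m)
  }
}

# four noiseless replicate runs of one sample/region from a size vector
fourRuns <- function(sizes, sample = "S1", region = "first",
                     height = 1000) {
  runs <- list()
  for (amp in c("A1", "A2")) for (dil in c("D1", "D2"))
    runs[[length(runs) + 1L]] <- CERun(sample, region, amp, dil,
      peaks = data.frame(size = sizes, height = height))
  runs
}

# canonical bipartition key of a species' accession set, relative to the
# reference tip used by bootstrapSupport (alphabetically first tip)
speciesSplitKey <- function(metadata, species) {
  acc <- sort(metadata$SampleCode[metadata$Species == species])
  all <- sort(metadata$SampleCode)
  side <- if (all[1] %in% acc) setdiff(all, acc) else acc
  paste(sort(side), collapse = "|")
}
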