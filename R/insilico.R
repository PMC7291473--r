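#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement matchPattern IUPAC_CODE_MAP
NULL

#' The degenerate TBP primer set
#'
#' The four exon-anchored degenerate primers driving the TBP assay: Fex1 and
#' Rex1 flank the first beta-tubulin intron, Fin2 and Rin2 the second; the
#' combined (h-TBP) assay pairs Fex1 with Rin2 across both introns and the
#' second exon.
#'
#' @return a \code{\link[Biostrings]{DNAStringSet}} named Fex1, Rex1, Fin2,
#'   Rin2, with metadata columns \code{orientation} (forward/reverse) and
#'   \code{region}.
#' @examples
#' tbpPrimers()
#' @export
tbpPrimers <- function() {
  p <- DNAStringSet(c(
    Fex1 = "AACTGGGCBAARGGNCAYTAYAC",
    Rex1 = "ACCATRCAYTCRTCDGCRTTYTC",
    Fin2 = "GARAAYGCHGAYGARTGYATG",
    Rin2 = "CRAAVCCBACCATGAARAARTGT"))
  S4Vectors::mcols(p) <- DataFrame(
    orientation = c("forward", "reverse", "forward", "reverse"),
    region = c("first", "first", "second", "second"))
  p
}

.primerPair <- function(mode) {
  switch(mode,
         "first-intron" = c("Fex1", "Rex1"),
         "second-intron" = c("Fin2", "Rin2"),
         "h-TBP" = c("Fex1", "Rin2"),
         stop("unknown mode: ", mode))
}

#' Degeneracy of an IUPAC primer
#'
#' The number of concrete sequences a degenerate primer denotes: the product
#' over positions of the IUPAC set sizes (N = 4; B, D, H, V = 3; two-base
#' codes = 2; plain bases = 1).
#'
#' @param primer character or \code{DNAString} over the IUPAC alphabet.
#' @return integer count.
#' @examples
#' iupacDegeneracy("AN")                      # 4
#' iupacDegeneracy(tbpPrimers()[["Fex1"]])    # 96
#' @export
iupacDegeneracy <- function(primer) {
  s <- toupper(as.character(primer))
  ch <- strsplit(s, "")[[1]]
  sets <- IUPAC_CODE_MAP[ch]
  if (anyNA(sets))
    stop("illegal IUPAC symbol '", ch[which(is.na(sets))[1]],
         "' at position ", which(is.na(sets))[1])
  prod(nchar(sets))
}

# 4-bit encoding of IUPAC sets; under the strict policy a subject N carries
# no bits, so it intersects nothing and always counts as a mismatch
.iupacBits <- function(x) {
  base <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  bits <- vapply(IUPAC_CODE_MAP, function(s)
    sum(base[strsplit(s, "")[[1]]]), integer(1))
  ch <- strsplit(toupper(as.character(x)), "")[[1]]
  b <- bits[ch]
  b[is.na(b)] <- 0L
  unname(b)
}

.strictMismatches <- function(primerBits, windowChars) {
  base <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  sb <- base[windowChars]
  sb[is.na(sb)] <- 0L  # subject N (or anything odd) matches nothing
  sum(bitwAnd(primerBits, sb) == 0L)
}

#' Find degenerate-primer annealing sites
#'
#' A position matches when at every primer position the IUPAC set of the
#' primer symbol intersects the base of the target, allowing up to
#' \code{maxMismatch} violations. An N in the target sequence matches
#' nothing (always a mismatch). Reverse-orientation hits are sites where the
#' reverse complement of the primer occurs on the forward strand (the primer
#' anneals to the plus strand); their coordinates are reported on the
#' forward strand. Coordinates are 1-based and inclusive, the Bioconductor
#' convention.
#'
#' @param subject a \code{DNAString} or character sequence over A/C/G/T/N.
#' @param primer IUPAC primer (character or \code{DNAString}).
#' @param maxMismatch maximum tolerated mismatches (default 0).
#' @param strand \code{"both"} (default), \code{"+"} or \code{"-"}.
#' @return data.frame: \code{start}, \code{end}, \code{strand},
#'   \code{mismatches}; empty when the primer is longer than the subject.
#' @export
findPrimerSites <- function(subject, primer, maxMismatch = 0,
                            strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  stopifnot(maxMismatch >= 0)
  subj <- if (is(subject, "DNAString")) subject else DNAString(as.character(subject))
  prim <- if (is(primer, "DNAString")) primer else DNAString(as.character(primer))
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer())
  if (length(prim) > length(subj)) return(empty)
  subjChars <- strsplit(toupper(as.character(subj)), "")[[1]]

  scan1 <- function(pat, strandLabel) {
    hits <- matchPattern(pat, subj, max.mismatch = maxMismatch,
                         fixed = "subject")
    if (!length(hits)) return(empty)
    st <- Biostrings::start(hits); en <- Biostrings::end(hits)
    ok <- st >= 1L & en <= length(subj)
    st <- st[ok]; en <- en[ok]
    pb <- .iupacBits(pat)
    mm <- vapply(seq_along(st), function(k)
      .strictMismatches(pb, subjChars[st[k]:en[k]]), integer(1))
    keep <- mm <= maxMismatch
    data.frame(start = st[keep], end = en[keep],
               strand = rep(strandLabel, sum(keep)),
               mismatches = mm[keep])
  }
  out <- empty
  if (strand %in% c("both", "+")) out <- rbind(out, scan1(prim, "+"))
  if (strand %in% c("both", "-"))
    out <- rbind(out, scan1(reverseComplement(prim), "-"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict TBP amplicons in silico
#'
#' Scans sequences for sites of the degenerate primer pair of the chosen
#' assay mode and reports every virtual PCR product: a forward-primer site
#' paired with a downstream reverse-primer site on the same sequence, in
#' either template orientation (\code{strand} records which), with the
#' product length (inclusive of both primer footprints -- the full labelled
#' fragment that CE sizes) inside the plausible PCR range.
#'
#' @param seqs a \code{DNAStringSet}, named character vector of sequences,
#'   or path to a FASTA file.
#' @param mode \code{"first-intron"} (Fex1+Rex1), \code{"second-intron"}
#'   (Fin2+Rin2) or \code{"h-TBP"} (Fex1+Rin2).
#' @param maxMismatch primer mismatches tolerated (default 0; the primers
#'   are already degenerate).
#' @param minLen,maxLen product length bounds in bp (defaults 50, 2000).
#' @return data.frame: \code{seqId}, \code{mode}, \code{start}, \code{end}
#'   (1-based inclusive), \code{length}, \code{strand},
#'   \code{fwdMismatches}, \code{revMismatches}. Zero rows is a legal
#'   result.
#' @export
predictAmplicons <- function(seqs,
                             mode = c("first-intron", "second-intron",
                                      "h-TBP"),
                             maxMismatch = 0, minLen = 50, maxLen = 2000) {
  mode <- match.arg(mode)
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- readDNAStringSet(seqs)
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  primers <- tbpPrimers()
  pair <- .primerPair(mode)
  pairUp <- function(id, up, dn, upMm, dnMm, strandLabel) {
    # product spans from an upstream primer site to a downstream one
    if (!nrow(up) || !nrow(dn)) return(NULL)
    grid <- expand.grid(ui = seq_len(nrow(up)), di = seq_len(nrow(dn)))
    len <- dn$end[grid$di] - up$start[grid$ui] + 1L
    ok <- up$start[grid$ui] < dn$start[grid$di] &
      len >= minLen & len <= maxLen
    if (!any(ok)) return(NULL)
    grid <- grid[ok, , drop = FALSE]
    data.frame(seqId = id, mode = mode,
               start = up$start[grid$ui], end = dn$end[grid$di],
               length = dn$end[grid$di] - up$start[grid$ui] + 1L,
               strand = strandLabel,
               fwdMismatches = upMm$mismatches[grid[[upMm$which]]],
               revMismatches = dnMm$mismatches[grid[[dnMm$which]]])
  }
  out <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    fwd <- findPrimerSites(s, primers[[pair[1]]], maxMismatch)
    rev <- findPrimerSites(s, primers[[pair[2]]], maxMismatch)
    # template in forward orientation: fwd "+" upstream of rev "-"
    plus <- pairUp(id, fwd[fwd$strand == "+", ], rev[rev$strand == "-", ],
                   list(mismatches = fwd$mismatches[fwd$strand == "+"],
                        which = "ui"),
                   list(mismatches = rev$mismatches[rev$strand == "-"],
                        which = "di"), "+")
    # template in reverse orientation: rev "+" upstream of fwd "-"
    minus <- pairUp(id, rev[rev$strand == "+", ], fwd[fwd$strand == "-", ],
                    list(mismatches = fwd$mismatches[fwd$strand == "-"],
                         which = "di"),
                    list(mismatches = rev$mismatches[rev$strand == "+"],
                         which = "ui"), "-")
    rbind(plus, minus)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(seqId = character(), mode = character(),
                      start = integer(), end = integer(),
                      length = integer(), strand = character(),
                      fwdMismatches = integer(), revMismatches = integer())
  rownames(out) <- NULL
  out
}

#' Turn predicted amplicons into a virtual CE profile
#'
#' One peak per distinct product length (ties merged; the support column
#' counts how many amplicons share the length). Sizes are exact integers,
#' ready for [binMarkers()].
#'
#' @param amplicons data.frame from [predictAmplicons()] (one mode).
#' @param sampleCode sample identifier for the resulting profile.
#' @param region intron region of the profile; defaults to the region the
#'   mode amplifies (h-TBP products are filed under \code{"first"} unless
#'   stated otherwise).
#' @return a [ConsensusProfile-class].
#' @export
virtualProfile <- function(amplicons, sampleCode, region = NULL) {
  mode <- unique(amplicons$mode)
  if (length(mode) > 1L) stop("amplicons must come from one mode")
  if (is.null(region)) {
    region <- if (length(mode) && mode == "second-intron") "second" else "first"
  }
  if (!nrow(amplicons))
    return(ConsensusProfile(sampleCode, region))
  tab <- table(amplicons$length)
  ConsensusProfile(sampleCode, region,
                   peaks = data.frame(size = as.numeric(names(tab)),
                                      support = as.integer(tab),
                                      meanHeight = NA_real_))
}

#' Reference beta-tubulin exon model
#'
#' The typical plant beta-tubulin coding structure underlying TBP: three
#' exons of 396, 276 and 668 bp (1340 bp of coding sequence) separated by
#' the two polymorphic introns.
#'
#' @param first,second,third exon lengths in bp.
#' @return list of class \code{"exonModel"} with the three lengths and
#'   \code{total} (their sum).
#' @examples
#' exonModel()$total   # 1340
#' @export
exonModel <- function(first = 396, second = 276, third = 668) {
  if (any(c(first, second, third) <= 0)) stop("exon lengths must be positive")
  structure(list(first = first, second = second, third = third,
                 total = first + second + third),
            class = "exonModel")
}
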