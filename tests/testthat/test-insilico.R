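test_that("IUPAC degeneracy multiplies the per-symbol set sizes", {
  expect_equal(iupacDegeneracy("ACGT"), 1)
  expect_equal(iupacDegeneracy("AN"), 4)
  p <- tbpPrimers()
  for (nm in names(p)) {
    # oracle: count the explicit expansions
    expect_equal(iupacDegeneracy(p[[nm]]), length(expandIUPAC(p[[nm]])))
  }
  expect_equal(iupacDegeneracy(p[["Fex1"]]), 96)
  expect_error(iupacDegeneracy("ACXG"), "position 3")
})

test_that("primer sites obey self-match, strand and mismatch contracts", {
  set.seed(107)
  p <- tbpPrimers()
  fex <- p[["Fex1"]]
  exp1 <- expandIUPAC(fex)[17]
  pad <- function(s) paste0(paste(sample(c("A", "C", "G", "T"), 30,
                                         TRUE), collapse = ""), s,
                            paste(sample(c("A", "C", "G", "T"), 30,
                                         TRUE), collapse = ""))
  s1 <- pad(exp1)
  hits <- findPrimerSites(s1, fex)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$start, 31L)
  expect_equal(fwd$mismatches, 0L)

  # reverse-orientation: a Rex1 expansion's reverse complement on the
  # forward strand is a "-" hit
  rex <- p[["Rex1"]]
  rcSite <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(expandIUPAC(rex)[5])))
  s2 <- pad(rcSite)
  h2 <- findPrimerSites(s2, rex)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 31L)

  # one substitution: invisible at 0 mismatches, found with 1
  mut <- s1
  substr(mut, 35, 35) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s1, 35, 35))[1]
  expect_equal(nrow(findPrimerSites(mut, fex, maxMismatch = 0)[
    findPrimerSites(mut, fex, maxMismatch = 0)$strand == "+", ]), 0L)
  h3 <- findPrimerSites(mut, fex, maxMismatch = 1)
  h3 <- h3[h3$strand == "+", ]
  expect_equal(h3$mismatches, 1L)

  # N in the target matches nothing
  nSeq <- s1
  substr(nSeq, 35, 35) <- "N"
  expect_equal(sum(findPrimerSites(nSeq, fex, 0)$strand == "+"), 0L)

  # primer longer than the sequence: empty result, not an error
  expect_equal(nrow(findPrimerSites("ACGT", fex)), 0L)
})

test_that("the matcher equals brute-force expansion matching", {
  set.seed(109)
  p <- tbpPrimers()
  for (nm in names(p)) {
    prim <- p[[nm]]
    site <- expandIUPAC(prim)[sample(iupacDegeneracy(prim), 1)]
    seq <- paste0(paste(sample(c("A", "C", "G", "T", "N"), 40, TRUE,
                               prob = c(rep(0.24, 4), 0.04)),
                        collapse = ""),
                  site,
                  paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                        collapse = ""))
    for (mm in 0:2) {
      mine <- findPrimerSites(seq, prim, maxMismatch = mm, strand = "+")
      expect_equal(mine$start, bruteSites(seq, prim, mm))
    }
  }
  # random degenerate primers of modest degeneracy
  for (rep in 1:5) {
    prim <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N"), 10, TRUE,
                         prob = c(rep(0.2, 4), 0.08, 0.08, 0.04)),
                  collapse = "")
    if (iupacDegeneracy(prim) > 96) next
    seq <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    for (mm in 0:1) {
      mine <- findPrimerSites(seq, prim, maxMismatch = mm, strand = "+")
      expect_equal(mine$start, bruteSites(seq, prim, mm))
    }
  }
})

test_that("match sets grow with the mismatch allowance", {
  set.seed(113)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  fex <- tbpPrimers()[["Fex1"]]
  prev <- findPrimerSites(seq, fex, maxMismatch = 2)
  for (mm in 3:4) {
    cur <- findPrimerSites(seq, fex, maxMismatch = mm)
    expect_true(all(paste(prev$start, prev$strand) %in%
                    paste(cur$start, cur$strand)))
    prev <- cur
  }
})

test_that("constructed Fex1/Rex1 template yields the exact 146-bp product", {
  set.seed(127)
  p <- tbpPrimers()
  fexExp <- expandIUPAC(p[["Fex1"]])[1]
  rexRc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(expandIUPAC(p[["Rex1"]])[1])))
  spacer <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  seq <- Biostrings::DNAStringSet(c(tpl = paste0(fexExp, spacer, rexRc)))
  amp <- predictAmplicons(seq, "first-intron")
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 146L)   # 23 + 100 + 23
  expect_equal(amp$start, 1L)
  expect_equal(amp$end, 146L)

  # two forward sites sharing one reverse site give two products
  seq2 <- Biostrings::DNAStringSet(c(two = paste0(
    fexExp, spacer, fexExp, spacer, rexRc)))
  expect_equal(nrow(predictAmplicons(seq2, "first-intron")), 2L)

  # length bounds cut products
  expect_equal(nrow(predictAmplicons(seq, "first-intron", maxLen = 100)),
               0L)
  expect_equal(nrow(predictAmplicons(seq, "first-intron", minLen = 200)),
               0L)
})

test_that("virtual profiles deduplicate lengths and stay bin-ready", {
  amp <- data.frame(seqId = c("g1", "g2", "g3"), mode = "first-intron",
                    start = 1L, end = c(146L, 146L, 300L),
                    length = c(146L, 146L, 300L), strand = "+",
                    fwdMismatches = 0L, revMismatches = 0L)
  vp <- virtualProfile(amp, "S1")
  expect_equal(profilePeaks(vp)$size, c(146, 300))
  expect_equal(profilePeaks(vp)$support, c(2L, 1L))
  expect_equal(intronRegion(vp), "first")

  empty <- virtualProfile(amp[0, ], "S1")
  expect_equal(nrow(profilePeaks(empty)), 0L)
})

test_that("amplicon length multisets are strand-symmetric", {
  gf <- simulateGeneFamily(5, seed = 131)
  rc <- Biostrings::reverseComplement(gf$sequences)
  for (mode in c("first-intron", "second-intron", "h-TBP")) {
    a1 <- predictAmplicons(gf$sequences, mode)
    a2 <- predictAmplicons(rc, mode)
    expect_equal(sort(a1$length), sort(a2$length))
  }
})

test_that("the exon model sums its in-frame lengths", {
  em <- exonModel()
  expect_equal(em$total, em$first + em$second + em$third)
  expect_equal(c(em$first, em$second, em$third), c(396, 276, 668))
  expect_equal(em$total, 1340)
  expect_error(exonModel(first = -1), "positive")
})
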