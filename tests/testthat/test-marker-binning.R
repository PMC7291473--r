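profOf <- function(code, sizes, region = "first") {
  ConsensusProfile(code, region,
                   peaks = data.frame(size = sizes,
                                      support = rep(4L, length(sizes)),
                                      meanHeight = rep(1000, length(sizes))))
}

test_that("ascending-size binning reproduces hand-clustered examples", {
  m <- binMarkers(list(profOf("A", c(302.1, 450.0)),
                       profOf("B", c(302.8, 455.2))), gapTolBp = 1.0)
  expect_equal(nrow(m), 3L)
  expect_equal(unname(presence(m)[, "A"]), c(1L, 1L, 0L))
  expect_equal(unname(presence(m)[, "B"]), c(1L, 0L, 1L))
  expect_equal(markerBins(m)$center[1], mean(c(302.1, 302.8)))

  ident <- binMarkers(list(profOf("A", 500), profOf("B", 500)))
  expect_equal(nrow(ident), 1L)
  expect_true(all(presence(ident) == 1L))
})

test_that("single-linkage chaining can span more than the gap tolerance", {
  m <- binMarkers(list(profOf("A", 100.0), profOf("B", 100.9),
                       profOf("C", 101.8)), gapTolBp = 1.0)
  expect_equal(nrow(m), 1L)
  b <- markerBins(m)
  expect_equal(b$maxSize - b$minSize, 1.8)

  # a chain wider than 2x the tolerance raises the width warning
  expect_warning(
    w <- binMarkers(list(profOf("A", 100.0), profOf("B", 100.9),
                         profOf("C", 101.8), profOf("D", 102.7)),
                    gapTolBp = 1.0),
    "chaining")
  expect_equal(nrow(w), 1L)
})

test_that("binning matches the exhaustive single-linkage oracle", {
  set.seed(47)
  for (rep in 1:30) {
    n <- sample(2:15, 1)
    sizes <- sort(round(runif(n, 100, 140), 2))
    samples <- paste0("s", seq_len(n))  # one peak per sample: pure clustering
    gapTol <- runif(1, 0.5, 6)
    m <- suppressWarnings(binMarkers(
      lapply(seq_len(n), function(k) profOf(samples[k], sizes[k])),
      gapTolBp = gapTol))
    oracle <- oracleGapBins(sizes, gapTol)
    expect_equal(nrow(m), length(unique(oracle)))
    # same partition: peaks sharing an oracle cluster share a bin
    bins <- markerBins(m)
    binOf <- vapply(sizes, function(s)
      which(s >= bins$minSize & s <= bins$maxSize), integer(1))
    expect_equal(as.integer(factor(binOf)),
                 as.integer(factor(oracle, levels = unique(oracle))))
  }
})

test_that("membership is shift-invariant and monotone in the tolerance", {
  set.seed(53)
  profs <- lapply(1:5, function(k)
    profOf(paste0("s", k), sort(sample(seq(100, 400, by = 3),
                                       sample(3:8, 1)))))
  m0 <- suppressWarnings(binMarkers(profs, gapTolBp = 2))
  shifted <- lapply(profs, function(p) {
    pk <- profilePeaks(p)
    pk$size <- pk$size + 1000
    ConsensusProfile(sampleCode(p), intronRegion(p), peaks = pk)
  })
  m1 <- suppressWarnings(binMarkers(shifted, gapTolBp = 2))
  expect_identical(unname(presence(m1)), unname(presence(m0)))
  expect_equal(markerBins(m1)$center, markerBins(m0)$center + 1000)

  nBins <- vapply(c(0.5, 1, 2, 4, 8), function(tol)
    nrow(suppressWarnings(binMarkers(profs, gapTolBp = tol))), integer(1))
  expect_true(all(diff(nBins) <= 0))
  expect_error(binMarkers(profs, gapTolBp = 0), "gapTolBp")
})

test_that("one sample with two peaks in a bin collapses with a warning", {
  expect_warning(
    m <- binMarkers(list(profOf("A", c(200.0, 200.5)), profOf("B", 200.2))),
    "collapsed")
  expect_equal(nrow(m), 1L)
  expect_true(all(presence(m) == 1L))
})

test_that("region combination concatenates markers and guards samples", {
  m1 <- binMarkers(lapply(c("A", "B", "C"), function(s)
    profOf(s, c(100, 200) + match(s, c("A", "B", "C")) * 10)))
  m2 <- binMarkers(lapply(c("A", "B", "C"), function(s)
    profOf(s, c(500, 600, 700) + match(s, c("A", "B", "C")) * 10, "second")))
  comb <- combineRegions(m1, m2)
  expect_equal(nrow(comb), nrow(m1) + nrow(m2))
  expect_identical(sampleCodes(comb), c("A", "B", "C"))
  expect_equal(markerBins(comb)$region,
               c(rep("first", nrow(m1)), rep("second", nrow(m2))))

  # sample in one region only: dropped by default, NA-kept on request
  m2b <- binMarkers(lapply(c("A", "B"), function(s)
    profOf(s, 500, "second")))
  expect_warning(d <- combineRegions(m1, m2b), "C")
  expect_identical(sampleCodes(d), c("A", "B"))
  expect_warning(k <- combineRegions(m1, m2b, missing = "na"), "C")
  expect_true(anyNA(presence(k)[, "C"]))

  # disjoint sample sets: refuse
  m2c <- binMarkers(list(profOf("X", 500, "second")))
  expect_error(suppressWarnings(combineRegions(m1, m2c)), "no samples")
})

test_that("peak counts per region sum to the reported totals", {
  # per-accession totals behave like the published peanut panel arithmetic:
  # e.g. 11 first-region + 15 second-region = 26; 6 + 9 = 15
  mk <- function(code, n1, n2) {
    list(profOf(code, seq(100, by = 10, length.out = n1), "first"),
         profOf(code, seq(500, by = 10, length.out = n2), "second"))
  }
  profs <- c(mk("tetra", 11, 15), mk("dip", 6, 9))
  cs <- peakCountSummary(profs)
  cs <- cs[order(cs$Sample), ]
  expect_equal(cs$Total[cs$Sample == "tetra"], 26)
  expect_equal(cs$Total[cs$Sample == "dip"], 15)
  expect_equal(cs$first, c(6, 11))  # dip, tetra after sorting

  # and identically from the combined matrix
  m <- combineRegions(
    binMarkers(list(profs[[1]], profs[[3]])),
    binMarkers(list(profs[[2]], profs[[4]])))
  cm <- peakCountSummary(m)
  expect_equal(sort(cm$Total), c(15, 26))

  empty <- peakCountSummary(list(profOf("E", numeric(0))))
  expect_equal(empty$Total, 0)
})

test_that("polymorphic markers are those both present and absent", {
  m <- matrix(1L, 3, 10, dimnames = list(c("A", "B", "C"), NULL))
  m[1, 4:10] <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L)  # 3 monomorphic all-1 cols
  m[2, 4:10] <- c(1L, 0L, 1L, 0L, 1L, 0L, 1L)
  mm <- MarkerMatrix(t(m), bins = data.frame(
    region = "first", center = 1:10 * 100, minSize = 1:10 * 100,
    maxSize = 1:10 * 100))
  pc <- polymorphicCount(mm)
  expect_equal(pc$nPolymorphic, 7L)
  expect_equal(pc$percentPolymorphic, 70)
  expect_error(polymorphicCount(t(matrix(1L, 1, 3))), "single-sample")
})
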