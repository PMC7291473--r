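test_that("a peak table reads back as sorted CERuns", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sample,Region,Amp,Dilution,Size,Height",
               "S1,1,A1,D1,302.1,1200",
               "S1,1,A1,D1,610.5,800",
               "S1,1,A1,D1,450.0,950"), tf)
  runs <- readPeakTable(tf)
  expect_length(runs, 1L)
  expect_equal(runPeaks(runs[[1]])$size, c(302.1, 450.0, 610.5))
  expect_equal(sampleCode(runs[[1]]), "S1")
  expect_equal(intronRegion(runs[[1]]), "first")
})

test_that("missing required columns and bad rows are surfaced", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sample,Size", "S1,302.1"), tf)
  expect_error(readPeakTable(tf), "Height")

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sample,Size,Height", "S1,302.1,100", "S1,oops,200",
               "S1,450,300"), tf2)
  expect_warning(runs <- readPeakTable(tf2), "unparseable")
  expect_equal(attr(runs, "badRows"), 2L)
  expect_equal(nrow(runPeaks(runs[[1]])), 2L)
})

test_that("duplicate peak rows keep the highest-RFU record", {
  df <- data.frame(Sample = "S1", Region = "1", Amp = "A1",
                   Dilution = "D1", Size = c(300, 300, 400),
                   Height = c(100, 900, 500))
  expect_warning(runs <- readPeakTable(df), "duplicate")
  p <- runPeaks(runs[[1]])
  expect_equal(p$height[p$size == 300], 900)
})

test_that("peak tables round-trip at full precision", {
  set.seed(11)
  sizes <- sort(runif(7, 60, 1100))
  runs <- list(CERun("S1", "first", "A1", "D1",
                     data.frame(size = sizes, height = rlnorm(7, 7, 0.5))),
               CERun("S2", "second", "A2", "D2",
                     data.frame(size = sizes + 0.123456789,
                                height = rep(100.5, 7))))
  tf <- withr::local_tempfile(fileext = ".csv")
  writePeakTable(runs, tf)
  back <- readPeakTable(tf)
  key <- function(rs) vapply(rs, function(r)
    paste(sampleCode(r), intronRegion(r)), character(1))
  back <- back[match(key(runs), key(back))]
  for (k in 1:2) {
    expect_equal(runPeaks(back[[k]])$size, runPeaks(runs[[k]])$size)
    expect_equal(runPeaks(back[[k]])$height, runPeaks(runs[[k]])$height)
  }
})

test_that("region tokens normalize and bad ones fail loudly", {
  expect_equal(normalizeRegion(c("1", "first", "TBPTD1i")),
               rep("first", 3))
  expect_equal(normalizeRegion(c("2", "second", "TBPTD2i")),
               rep("second", 3))
  expect_error(normalizeRegion("third"), "unrecognized")
})

test_that("size-standard validation matches the expected pattern", {
  std <- sizeStandard("demo", c(100, 200, 300))
  obs <- function(sizes) data.frame(size = sizes,
                                    height = rep(1000, length(sizes)))
  # identity: all matched, pass
  v <- validateSizeStandard(obs(c(100, 200, 300)), std)
  expect_true(v$pass)
  expect_true(all(v$fragments$matched))

  # missing middle fragment: fail, peaks between the flanks unsizeable
  v2 <- validateSizeStandard(obs(c(100, 300)), std)
  expect_false(v2$pass)
  expect_equal(v2$fragments$matched, c(TRUE, FALSE, TRUE))
  expect_false(v2$sizeable(250))
  expect_false(v2$sizeable(150))

  # within tolerance: 100.3 and 199.8 both match at 0.5 bp
  v3 <- validateSizeStandard(obs(c(100.3, 199.8)),
                             sizeStandard("d2", c(100, 200)),
                             sizeTolBp = 0.5)
  expect_true(v3$pass)
  expect_equal(v3$fragments$observedSize, c(100.3, 199.8))

  # fewer than 2 matches fails outright
  v4 <- validateSizeStandard(obs(105), std)
  expect_false(v4$pass)
})

test_that("shrinking the size tolerance never converts a fail into a pass", {
  set.seed(23)
  std <- sizeStandard("mono", seq(100, 600, by = 50))
  for (rep in 1:25) {
    o <- sort(std$sizes + rnorm(length(std$sizes), 0, 0.6))
    o <- o[runif(length(o)) > 0.2]
    obs <- data.frame(size = o, height = 1000)
    passes <- vapply(c(1.5, 1.0, 0.5, 0.25), function(tol)
      validateSizeStandard(obs, std, sizeTolBp = tol)$pass, logical(1))
    # once failed at a larger tolerance, smaller tolerances stay failed
    expect_equal(passes, as.logical(cummin(passes)))
  }
})

test_that("metadata cross-referencing lists offending codes", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SampleCode,Species", "S1,Arachis duranensis",
               "S2,Arachis hypogaea"), tf)
  meta <- readSampleMetadata(tf)
  expect_silent(checkSampleCodes(c("S1", "S2"), meta))
  expect_error(checkSampleCodes(c("S1", "S3"), meta), "S3")
})

test_that("the binary matrix CSV round-trips bit-exactly", {
  m <- MarkerMatrix(
    matrix(c(1L, 0L, 1L, 0L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L), 4,
           dimnames = list(NULL, c("A", "B", "C"))),
    bins = data.frame(region = c("first", "first", "second", "second"),
                      center = c(302.125, 450.5, 88.25, 912.4),
                      minSize = c(302.1, 450.5, 88.25, 912.4),
                      maxSize = c(302.15, 450.5, 88.25, 912.4)))
  tf <- withr::local_tempfile(fileext = ".csv")
  writeMarkerMatrix(m, tf)
  back <- readMarkerMatrix(tf)
  expect_identical(unname(presence(back)), unname(presence(m)))
  expect_identical(sampleCodes(back), sampleCodes(m))
  expect_equal(markerBins(back)$center, markerBins(m)$center)
  expect_equal(markerBins(back)$region, markerBins(m)$region)

  # empty matrix: header-only file, read back as empty
  e <- MarkerMatrix(matrix(integer(), 0, 2,
                           dimnames = list(NULL, c("A", "B"))),
                    bins = data.frame(region = character(),
                                      center = numeric(),
                                      minSize = numeric(),
                                      maxSize = numeric()))
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeMarkerMatrix(e, tf2)
  expect_equal(nrow(readMarkerMatrix(tf2)), 0L)
})
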