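#' True presence/absence matrix of a simulated panel
#'
#' Builds the ground-truth binary matrix (samples x marker sizes, both
#' regions side by side) directly from the generator's true profiles,
#' bypassing CE noise, consolidation and binning.
#'
#' @param panel result of [simulatePanel()].
#' @return binary matrix, samples as rows, one column per distinct true
#'   (region, size) marker.
#' @export
panelTruthMatrix <- function(panel) {
  pr <- panel$profiles
  marker <- paste(pr$region, pr$size, sep = ":")
  samples <- unique(pr$sample)
  markers <- unique(marker[order(pr$region, pr$size)])
  m <- matrix(0L, length(samples), length(markers),
              dimnames = list(samples, markers))
  m[cbind(pr$sample, marker)] <- 1L
  m
}

# one random concrete expansion of an IUPAC primer (uses the current RNG)
.sampleExpansion <- function(primer) {
  sets <- IUPAC_CODE_MAP[strsplit(toupper(as.character(primer)), "")[[1]]]
  paste(vapply(strsplit(sets, ""), function(s)
    s[sample.int(length(s), 1L)], character(1)), collapse = "")
}

.randomBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a beta-tubulin gene family with planted intron lengths
#'
#' Each simulated gene follows the reference coding structure
#' exon1(396) - intron1 - exon2(276) - intron2 - exon3(668), with one
#' concrete expansion of each degenerate primer planted at its exon-boundary
#' anchor: Fex1 ends exon 1, the conserved motif opening exon 2 is both the
#' Rex1 reverse site and the Fin2 forward site (Fin2 is an IUPAC prefix of
#' the reverse complement of Rex1 -- the two primers read the same conserved
#' exon-2 boundary, as in real beta-tubulin genes), and the Rin2 site opens
#' exon 3. Everything else is random A/C/G/T under the seed, so
#' [predictAmplicons()] recovers exactly one product per gene and mode, of
#' a length fixed by the planted introns: intron1 + 46 bp (first-intron
#' mode), intron2 + second exon + 23 (second-intron mode, the product
#' spanning exon 2), and intron1 + intron2 + second exon + 46 (h-TBP).
#'
#' @param nGenes number of gene-family members (>= 1).
#' @param intronLengths optional list with numeric vectors \code{intron1}
#'   and \code{intron2} (length \code{nGenes}, each in [50, 1800]); by
#'   default lengths are drawn without replacement from a 4-bp-spaced grid
#'   so distinct genes stay resolvable at the default binning tolerance.
#' @param seed integer seed; same seed, byte-identical output.
#' @param exons an [exonModel()].
#' @return list: \code{sequences} (\code{DNAStringSet}, one per gene) and
#'   \code{truth} (data.frame gene, intron1, intron2, ampliconFirst,
#'   ampliconSecond, ampliconHTBP).
#' @export
simulateGeneFamily <- function(nGenes, intronLengths = NULL, seed = NULL,
                               exons = exonModel()) {
  stopifnot(nGenes >= 1)
  .withSeed(seed, {
    if (is.null(intronLengths)) {
      grid <- seq(60, 1100, by = 4)
      intronLengths <- list(intron1 = sample(grid, nGenes),
                            intron2 = sample(grid, nGenes))
    }
    i1 <- intronLengths$intron1
    i2 <- intronLengths$intron2
    if (length(i1) != nGenes || length(i2) != nGenes)
      stop("need one intron1 and one intron2 length per gene")
    if (any(c(i1, i2) < 50) || any(c(i1, i2) > 1800))
      stop("intron lengths must lie in [50, 1800] bp")

    primers <- tbpPrimers()
    fex <- nchar(as.character(primers[["Fex1"]]))
    rex <- nchar(as.character(primers[["Rex1"]]))
    rin <- nchar(as.character(primers[["Rin2"]]))

    seqs <- vapply(seq_len(nGenes), function(g) {
      exon1 <- paste0(.randomBases(exons$first - fex),
                      .sampleExpansion(primers[["Fex1"]]))
      # one site, two roles: revcomp(Rex1 expansion) opens exon 2 and its
      # first 21 nt are a concrete Fin2 expansion
      rexSite <- as.character(reverseComplement(DNAString(
        .sampleExpansion(primers[["Rex1"]]))))
      exon2 <- paste0(rexSite, .randomBases(exons$second - rex))
      rinSite <- as.character(reverseComplement(DNAString(
        .sampleExpansion(primers[["Rin2"]]))))
      exon3 <- paste0(rinSite, .randomBases(exons$third - rin))
      paste0(exon1, .randomBases(i1[g]), exon2, .randomBases(i2[g]), exon3)
    }, character(1))
    names(seqs) <- sprintf("gene%02d", seq_len(nGenes))
    truth <- data.frame(gene = names(seqs), intron1 = i1, intron2 = i2,
                        ampliconFirst = i1 + fex + rex,
                        ampliconSecond = i2 + exons$second + rin,
                        ampliconHTBP = i1 + i2 + exons$second + fex + rin)
    list(sequences = DNAStringSet(seqs), truth = truth)
  })
}

#' Specification of a synthetic species panel
#'
#' Describes the study conditions a synthetic CE-TBP panel emulates: a few
#' species, a few accessions each, per-genome marker counts in the range
#' observed for diploid (8--10 genes per region pair) versus tetraploid
#' (up to 15 per region) material, plus two divergence dials -- the
#' per-accession marker dropout/gain rate (intra-specific noise) and the
#' between-species marker turnover rate.
#'
#' @param nSpecies number of species (default 3).
#' @param accessionsPerSpecies accessions per species: a single count
#'   (default 4) or one count per species.
#' @param ploidy integer vector (2 or 4) per species; tetraploids carry more
#'   markers. Default all diploid.
#' @param genesFirst,genesSecond markers per genome and region for diploids
#'   (defaults 8 and 10); tetraploids get 11 and 15.
#' @param intronRange amplicon size range (bp) markers are drawn from
#'   (default 100--1150).
#' @param dropout per-accession, per-marker dropout (and matching gain)
#'   probability (default 0.05).
#' @param turnover per-species, per-marker replacement probability relative
#'   to the genus founder set (default 0.5).
#' @param seed integer seed.
#' @return list of class \code{"panelSpec"}.
#' @export
panelSpec <- function(nSpecies = 3, accessionsPerSpecies = 4,
                      ploidy = rep(2L, nSpecies),
                      genesFirst = 8L, genesSecond = 10L,
                      intronRange = c(100, 1150),
                      dropout = 0.05, turnover = 0.5, seed = 1L) {
  if (length(accessionsPerSpecies) == 1L)
    accessionsPerSpecies <- rep(accessionsPerSpecies, nSpecies)
  stopifnot(nSpecies >= 1, all(accessionsPerSpecies >= 1),
            length(accessionsPerSpecies) == nSpecies,
            length(ploidy) == nSpecies, all(ploidy %in% c(2L, 4L)),
            dropout >= 0, dropout <= 1, turnover >= 0, turnover <= 1,
            genesFirst >= 1, genesSecond >= 1)
  structure(list(nSpecies = nSpecies,
                 accessionsPerSpecies = as.integer(accessionsPerSpecies),
                 ploidy = as.integer(ploidy),
                 genesFirst = as.integer(genesFirst),
                 genesSecond = as.integer(genesSecond),
                 intronRange = intronRange, dropout = dropout,
                 turnover = turnover, seed = seed),
            class = "panelSpec")
}

#' Simulate a species panel of true marker profiles
#'
#' Marker sizes live on a 4-bp-spaced grid (so truth stays unambiguous at
#' the 1-bp binning tolerance). A genus-wide founder marker set is drawn per
#' region; each species replaces founder markers with species-private sizes
#' at the turnover rate (tetraploid species carry proportionally more
#' markers); each accession then drops founder markers and gains private
#' ones at the dropout rate. With turnover > dropout the expected
#' intra-specific Whittaker dissimilarity sits below the inter-specific one,
#' the structure of a real single-genus panel.
#'
#' @param spec a [panelSpec()].
#' @return list: \code{profiles} (data.frame sample, region, size -- the
#'   true peak lists), \code{metadata} (SampleCode, Species, Ploidy),
#'   \code{truth} (list with founder and per-species marker sets).
#' @export
simulatePanel <- function(spec = panelSpec()) {
  stopifnot(inherits(spec, "panelSpec"))
  .withSeed(spec$seed, {
    grid <- seq(spec$intronRange[1], spec$intronRange[2], by = 4)
    regions <- c(first = spec$genesFirst, second = spec$genesSecond)
    speciesNames <- sprintf("species%02d", seq_len(spec$nSpecies))

    profiles <- NULL
    speciesSets <- list()
    founders <- list()
    for (rg in names(regions)) {
      nBase <- regions[[rg]]
      founder <- sort(sample(grid, nBase))
      founders[[rg]] <- founder
      pool <- setdiff(grid, founder)
      for (s in seq_len(spec$nSpecies)) {
        mult <- if (spec$ploidy[s] == 4L) 1.45 else 1
        nSp <- round(nBase * mult)
        set <- founder
        flip <- stats::runif(length(set)) < spec$turnover
        if (any(flip)) {
          repl <- sample(pool, sum(flip))
          pool <- setdiff(pool, repl)
          set[flip] <- repl
        }
        if (nSp > length(set)) {
          extra <- sample(pool, nSp - length(set))
          pool <- setdiff(pool, extra)
          set <- c(set, extra)
        }
        set <- sort(set)
        speciesSets[[paste(rg, speciesNames[s], sep = ".")]] <- set
        for (a in seq_len(spec$accessionsPerSpecies[s])) {
          code <- sprintf("%s.ac%02d", speciesNames[s], a)
          keep <- set[stats::runif(length(set)) >= spec$dropout]
          nGain <- stats::rbinom(1, length(set), spec$dropout)
          if (nGain > 0) {
            gain <- sample(setdiff(grid, c(set, keep)), nGain)
            keep <- c(keep, gain)
          }
          if (!length(keep)) keep <- set[1]  # never an empty profile
          profiles <- rbind(profiles,
                            data.frame(sample = code, region = rg,
                                       size = sort(keep)))
        }
      }
    }
    nAcc <- spec$accessionsPerSpecies
    metadata <- data.frame(
      SampleCode = sprintf("%s.ac%02d", rep(speciesNames, nAcc),
                           unlist(lapply(nAcc, seq_len))),
      Species = rep(speciesNames, nAcc),
      Ploidy = rep(spec$ploidy, nAcc))
    list(profiles = profiles, metadata = metadata,
         truth = list(founders = founders, speciesSets = speciesSets,
                      spec = spec))
  })
}

#' Simulate replicated noisy CE runs from true profiles
#'
#' Emulates the four-run replicate scheme (2 independent amplifications x 2
#' dilutions) of a CE-TBP experiment: every true amplicon size is jittered
#' by Normal(0, \code{jitterSdBp}) per run (CE sizing is fractional),
#' heights are drawn log-normal (right-skewed like real RFU distributions)
#' and clipped to [1, 40000], peaks drop out independently per run, and a
#' run can be made out-of-scale (one peak pushed above 32,000 RFU) with
#' probability \code{outOfScaleProb}.
#'
#' @param profiles data.frame (sample, region, size) as from
#'   [simulatePanel()].
#' @param jitterSdBp sizing jitter SD in bp (default 0.3).
#' @param heightMeanlog,heightSdlog log-normal height model parameters
#'   (defaults log(2000) and 0.8).
#' @param dropoutPerRun per-run, per-peak dropout probability (default
#'   0.02).
#' @param outOfScaleProb probability a run contains an out-of-scale peak
#'   (default 0).
#' @param seed integer seed.
#' @return data.frame in the default [peakDialect()] columns (Sample,
#'   Region, Amp, Dilution, Dye, Size, Height, Area), ready for
#'   [readPeakTable()] or [writePeakTable()].
#' @export
simulateCeRuns <- function(profiles, jitterSdBp = 0.3,
                           heightMeanlog = log(2000), heightSdlog = 0.8,
                           dropoutPerRun = 0.02, outOfScaleProb = 0,
                           seed = NULL) {
  stopifnot(all(c("sample", "region", "size") %in% names(profiles)))
  .withSeed(seed, {
    out <- NULL
    combos <- unique(profiles[c("sample", "region")])
    for (k in seq_len(nrow(combos))) {
      true <- profiles$size[profiles$sample == combos$sample[k] &
                            profiles$region == combos$region[k]]
      for (amp in c("A1", "A2")) for (dil in c("D1", "D2")) {
        keep <- stats::runif(length(true)) >= dropoutPerRun
        if (!any(keep)) next
        size <- true[keep] + stats::rnorm(sum(keep), 0, jitterSdBp)
        height <- pmin(pmax(stats::rlnorm(sum(keep), heightMeanlog,
                                          heightSdlog), 1), 40000)
        if (stats::runif(1) < outOfScaleProb)
          height[sample.int(length(height), 1)] <- 39000
        out <- rbind(out, data.frame(
          Sample = combos$sample[k], Region = combos$region[k],
          Amp = amp, Dilution = dil, Dye = "FAM",
          Size = size, Height = height, Area = NA_real_))
      }
    }
    out[order(out$Sample, out$Region, out$Amp, out$Dilution, out$Size), ,
        drop = FALSE]
  })
}
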