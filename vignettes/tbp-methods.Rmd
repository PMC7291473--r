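---
title: "CE-TBP genotyping: models, parameters and design decisions"
author: "tbptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CE-TBP genotyping: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbptools)
```

# The assay, in computational terms

Tubulin-Based Polymorphism (TBP) exploits the fact that plant β-tubulin
genes share strongly conserved exon sequences around introns of variable
length. Degenerate primers anchored in those exons amplify, in one
reaction, one product per gene-family member; a genome is summarized by
the multiset of product lengths. Resolved by capillary electrophoresis
(CE), the readout per sample is a list of peaks, each with a fractional
size in base pairs and a height in relative fluorescence units (RFU). The
reference coding structure behind the assay is three exons of 396, 276 and
668 bp (1340 bp coding) separated by the two polymorphic introns
(`exonModel()`).

Everything downstream is presence/absence statistics: peak sizes become
dominant binary markers, samples become rows of a binary matrix, and the
questions are (i) how dissimilar two fingerprints are, (ii) whether
within-species dissimilarity separates from between-species dissimilarity
(a barcoding gap), and (iii) whether distance-based trees and ordinations
recover the known taxonomy.

# Pipeline stages and their parameters

## Sizing QC

The co-injected ladder converts migration time to bp, so a run is only as
good as its ladder assignment. `validateSizeStandard()` matches each
expected ladder fragment to at most one observed standard peak within
`sizeTolBp` (closest pairs first, each side used once), after discarding
observed peaks below `relHeightMin` of the tallest standard peak. A sample
peak is *sizeable* only when both the immediately preceding and the
immediately subsequent ladder fragments matched; the run fails if any
expected fragment inside the sample's size range is unmatched, or if fewer
than two fragments matched at all.

Defaults `sizeTolBp = 0.5` bp and `relHeightMin = 0.1` are this package's
choices: CE sizing of long fragments is reproducible to a few tenths of a
bp, and a standard peak at a tenth of the ladder's typical intensity is
more plausibly noise than signal. The matching is deliberately monotone:
shrinking the tolerance can only remove matches, never turn a failing run
into a passing one (a property the test suite checks). The built-in
`defaultLadder()` is a *representative* 20–1200 bp ladder for tests and
demonstrations, not a vendor fragment list.

## RFU thresholds

`filterRun()` records only peaks whose height *exceeds* `minRfu = 50`
(strictly greater — a tie at exactly 50 is removed, matching the verb),
and excludes the entire run when any peak exceeds `maxRfu = 32000`,
because a saturated detector distorts the whole trace, not just the
saturated peak. Exclusion is per run, recoverable: the sample proceeds
with its remaining replicates, with a warning.

## Replicate consolidation

Each sample/region is measured four times: two independent amplifications
× two dilutions. How the four runs merge into one scored profile is not
dictated by the assay itself, so `consolidateRuns()` makes the rule
explicit and overridable: peaks pooled across surviving runs are clustered
by single linkage with a new cluster whenever the gap between consecutive
sizes exceeds `sizeTolBp = 1.0` bp; a cluster becomes a consensus peak only
if it contains peaks from at least `minSupport = 2` distinct runs **and**
from both amplifications whenever both amplifications still have surviving
runs. The both-amplifications requirement is the point of the replicate
design — a reproducible peak must appear in independent PCRs, not merely in
two dilutions of the same reaction. The consensus size is the mean of the
member sizes; 1.0 bp is a safe within-sample tolerance given sub-bp CE
precision.

## Marker binning

Across samples, `binMarkers()` pools all (sample, size) pairs of one
region, sorts ascending, and starts a new bin wherever the gap to the
previous size exceeds `gapTolBp = 1.0` bp — single-linkage chaining with a
gap cut, the computational form of "organize the sizes in ascending order
and call each distinct size a marker". Chaining means a bin can span more
than the tolerance; bins wider than `2 * gapTolBp` raise a warning so the
user can inspect them. If one sample contributes two peaks to a bin they
collapse to a single presence (the matrix is binary by definition) with a
collision warning. `combineRegions()` concatenates the two regions'
matrices marker-wise; samples present in only one region are dropped from
combined analyses by default (`missing = "na"` keeps them with explicit
missing cells) — imputing absence would fabricate signal.

## Diversity and the barcoding gap

The pairwise dissimilarity is Whittaker's beta measure
$\beta_W = S/\bar\alpha - 1$, with $S$ the union marker count of the pair
and $\bar\alpha$ the mean per-sample count; on binary data this equals
$(b+c)/(2a+b+c)$ for $a$ shared and $b, c$ private markers — 0 for
identical, 1 for disjoint fingerprints (it coincides with the Sørensen
dissimilarity on binary data, which makes results comparable across
software). The Shannon index is $H = -\sum_i p_i \ln p_i$; since the
literature rarely states what $p_i$ is taken over, `shannonIndex()` makes
the convention a *required* argument: under `"presence-frequency"`,
$p_i$ is marker $i$'s presence count divided by the group's total
presences. No other convention is currently implemented, but the argument
guarantees none is ever applied silently.

`partitionIntraInter()` splits all pairs by species label and quantifies
the barcoding gap as the fraction of all observations (intra or inter)
inside the closed interval [min(inter), max(intra)] — zero when the ranges
separate. This pooled-observation definition was chosen over
histogram-area overlaps because it is parameter-free (no binning of the
dissimilarity axis) and reproduces the "how many comparisons are
ambiguous" reading of a gap plot.

## Ordination, trees, bootstrap

PCA runs on the variance–covariance matrix of the samples-by-markers
matrix (mean-centered, never scaled): common and rare markers contribute
by their variance, which is the convention under which TBP ordinations are
reported. Percents of variance always sum to 100 over the retained
components; an all-identical panel is flagged `degenerate` rather than
producing NaNs.

`njTree()` is a Saitou–Nei neighbor-joining implementation with two
choices pinned for reproducibility: ties in the Q-criterion minimization
break to the lowest (i, j) index pair, and a negative branch length is
clamped to zero with the deficit moved to the sister branch, preserving
the joined pair's path length. On additive matrices the tree reproduces
the input distances to machine precision (tested against 50 random trees);
topologies agree with `ape::nj`, which the test suite uses as the
independent oracle rather than as the implementation.

`bootstrapSupport()` resamples *marker columns* with replacement — the
only exchangeable unit of a binary marker matrix — recomputes distances
and the NJ tree, and scores each internal edge of the reference tree by
the percentage of replicates containing the same leaf bipartition.
Replicates that leave a sample with no markers are redrawn and counted.
Samples are put in canonical (sorted) order before any tree is built, so
supports do not depend on input column order; `seed` makes the whole
procedure deterministic, and the caller's RNG state is restored.

Two matrix-fit statistics are provided because published "cophenetic
correlations" mean either: `copheneticCorrelation()` correlates a tree's
path-length distances with the source matrix (degree of fit of a tree),
and `matrixCorrelation()` is a Mantel test between two independently
estimated distance matrices (e.g. the two intron regions), with a
one-sided permutation p-value, $p = (1 + \#\{r_{perm} \ge r\})/(n+1)$,
under an explicit seed and permutation count. Reports name which one was
used.

## In-silico TBP

`findPrimerSites()` treats every primer symbol as its IUPAC set: a
position matches when every set intersects the target base, with up to
`maxMismatch` violations; an `N` in the *target* matches nothing (a
degenerate primer is a known set of concrete oligos; an unknown base is
not evidence of annealing). Matching runs on the `Biostrings::matchPattern`
engine with strict mismatch recounting, and is verified against brute-force
expansion matching in the tests. `maxMismatch = 0` by default — the primers
are already degenerate; tolerance is exposed but off. Coordinates are
1-based inclusive, the Bioconductor convention used by every container
this package interoperates with. `predictAmplicons()` pairs upstream
forward-primer sites with downstream reverse-primer sites in either
template orientation and reports the full labelled product length
(both primer footprints included — that is what CE sizes), bounded to
[`minLen` = 50, `maxLen` = 2000] bp by default; h-TBP products span both
introns plus the 276-bp second exon and can legitimately exceed 2000 bp,
so recovery analyses widen `maxLen`. No thermodynamics are modeled
(melting temperature, 3'-end stability): annealing energetics belong to
the wet-lab protocol, not to a length predictor.

# The synthetic-data generator

The generator exists so the whole pipeline is testable without instrument
data, and its defaults are the study conditions under which the package's
claims are verified.

`simulateGeneFamily()` builds genes as
exon1(396)–intron1–exon2(276)–intron2–exon3(668) with concrete expansions
of the primers planted at their anchors. One structural fact is worth
stating: Fin2 is an IUPAC prefix of the reverse complement of Rex1 — both
primers read the same conserved exon-2 boundary motif. The generator
therefore plants a single exon-2 start motif serving as both the Rex1
reverse site and the Fin2 forward site; a second, independent Fin2 site
at the exon-2 end would duplicate the motif and yield two second-intron
products per gene. Consequently the second-intron product spans exon 2:
its length is intron2 + 276 + 23, while the first-intron product is
intron1 + 46 and the h-TBP product intron1 + intron2 + 322. True intron
lengths are drawn without replacement from a 4-bp-spaced grid in
[60, 1100] bp so ground truth stays unambiguous at the 1-bp binning
tolerance.

`simulatePanel()` generates marker-space truth: a genus founder set per
region (8 first-region and 10 second-region markers per diploid genome,
scaled ×1.45 for tetraploids, mirroring the observed 13–26 peaks per
accession across ploidies), species sets derived by replacing founder
markers at the `turnover = 0.5` rate, and accession profiles derived by
dropping/gaining markers at the `dropout = 0.05` rate. Whenever
turnover > dropout the expected intra-specific dissimilarity sits below
the inter-specific one, which is the single-genus structure the gap
analysis is meant to detect. The default panel is 3 species × 4
accessions; the acceptance script additionally uses a 17-accession /
8-species panel with one 7-accession tetraploid crop species and one
4-accession wild species, the sampling shape of a real single-genus study
group.

`simulateCeRuns()` emulates the replicate scheme (2 amplifications × 2
dilutions) with per-run sizing jitter Normal(0, `jitterSdBp = 0.3`),
log-normal heights (meanlog = ln 2000, sdlog = 0.8 — right-skewed like
real RFU distributions, occasionally exceeding the 32,000 RFU saturation
threshold, which exercises the exclusion path), per-run peak dropout at
0.02, and an optional forced out-of-scale peak.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: stutter and minus-A artefacts, size-dependent
signal decay, co-migrating fragments of different sequence, heteroduplex
peaks, primer mismatches in diverged genomes, and any correlation between
peak height and gene copy number. Results on synthetic panels demonstrate
that the *computations* are correct and that the pipeline recovers planted
structure under realistic noise magnitudes; they are not evidence about
any particular organism.

# Numerical choices and degenerate inputs

* Sizes are fractional bp everywhere and never rounded at ingest; marker
  bin centers are means of member sizes, written at full precision so CSV
  round trips are bit-exact.
* All-zero marker profiles make βW undefined (the $\bar\alpha$ term); they
  are an explicit error naming the sample, and bootstrap replicates that
  create one are redrawn.
* Duplicate peak rows (same run and size) keep the highest-RFU record,
  with a warning; unparseable rows are reported, never silently dropped.
* Empty results are legal where the science says so (zero amplicons, an
  empty marker matrix); "no surviving runs" is a flagged state, not an
  empty profile.
* The Q-matrix tie-break and the canonical sample ordering in the
  bootstrap exist purely to make results independent of input order.

# Problem sizes

The test suite enumerates all binary pairs up to 8 markers for the
Whittaker oracle, uses 50 random 4–12-taxon trees for NJ additivity, 6×10
matrices for the PCA oracle, ≤ 15 peaks for the binning oracle, and the
real primer set (degeneracy 72–96) for the matcher oracle. Pipeline-level
checks run panels of 12–17 samples with 200–1000 bootstrap replicates and
a 999-permutation Mantel test; the acceptance script uses 1000 replicates
throughout. These sizes were chosen so each check has enough structure to
fail informatively while the whole suite stays interactive.

# Known limitations

* Dominant markers only: no codominant allele calling, no dosage from
  peak heights, no ploidy inference beyond the qualitative marker-count
  trend.
* The consolidation rule (support ≥ 2 + both amplifications) is a stated
  convention, not a property of the assay; alternative rules are a
  parameter away but results will differ near the detection limit.
* Single-linkage binning chains: two markers 0.9 bp apart in adjacent
  samples merge even if the bin ends up 2 bp wide. The width warning
  surfaces these cases; a fixed-width binning is deliberately not offered
  because it splits clusters at arbitrary boundaries.
* The barcoding-gap overlap is a pooled-observation fraction, not a
  density overlap; with very unbalanced intra/inter counts the two can
  diverge.
* In-silico predictions assume perfect annealing at ≤ `maxMismatch`
  mismatches and ignore PCR competition between products.
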