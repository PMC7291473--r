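# tbptools

Tubulin-Based Polymorphism (TBP) genotyping from capillary-electrophoresis
fragment data.

## The problem

TBP fingerprints a plant genome through the length polymorphism of the two
introns of its β-tubulin gene family. Degenerate primers anchored in the
conserved exon sequences (Fex1/Rex1 for the first intron, Fin2/Rin2 for the
second, Fex1+Rin2 for the combined h-TBP assay) amplify one product per
gene-family member; the multiset of product lengths, resolved by capillary
electrophoresis (CE) as a pherogram of peaks with size (bp) and height
(RFU), is a genome fingerprint that discriminates taxa from genera down to
cultivars and ecotypes — with no prior sequence knowledge of the target
genome.

`tbptools` is for anyone running or evaluating this assay: it covers the
full computational path from the fragment-analysis peak table to the
published statistics, plus an in-silico predictor and a synthetic-data
generator so every stage can be exercised without a sequencer.

## What it computes

Given per-run peak tables (`readPeakTable()`), the pipeline:

1. validates runs against the co-injected size standard
   (`validateSizeStandard()`): a sample peak is sizeable only when both
   flanking ladder fragments were assigned correctly;
2. applies the RFU thresholds (`filterRun()`): only peaks **exceeding
   50 RFU** are recorded; a peak above **32,000 RFU** is out of scale and
   excludes the whole run;
3. consolidates the four replicate runs per sample/region
   (2 independent amplifications × 2 dilutions, `consolidateRuns()`):
   a consensus peak needs support from ≥ 2 runs *and* both amplifications;
4. bins consensus sizes in ascending order into markers
   (`binMarkers()`, single-linkage with a 1-bp gap cut) and scores the
   binary presence/absence matrix (`MarkerMatrix`, a
   `SummarizedExperiment`);
5. derives the statistics: pairwise **Whittaker dissimilarity**
   βW = S/ᾱ − 1 = (b+c)/(2a+b+c) (`whittakerDist()`), **Shannon index**
   H = −Σ pᵢ ln pᵢ over marker presence frequencies (`shannonIndex()`),
   the intra/inter-specific partition and **barcoding-gap overlap**
   (`partitionIntraInter()`), covariance-matrix **PCA**
   (`pcaCovariance()`), **neighbor-joining** trees with column-resampling
   **bootstrap** support (`njTree()`, `bootstrapSupport()`), cophenetic fit
   and Mantel matrix correlations (`copheneticCorrelation()`,
   `matrixCorrelation()`).

`predictAmplicons()` predicts TBP products from FASTA sequence using the
degenerate primers (IUPAC-aware matching, both template orientations), and
`simulateGeneFamily()` / `simulatePanel()` / `simulateCeRuns()` generate
β-tubulin gene families, species panels with controlled intra/inter
divergence, and noisy replicated CE peak tables.

## Worked example

```r
library(tbptools)

panel  <- simulatePanel(panelSpec(seed = 11))      # 3 species x 4 accessions
peaks  <- simulateCeRuns(panel$profiles, seed = 12) # 2 amps x 2 dilutions
report <- runTbpPipeline(peaks, metadata = panel$metadata,
                         bootstrapReps = 1000, seed = 13)
report
```

```
CE-TBP pipeline report
  runs: 96 ( 1 excluded )
  samples: 12  markers: 53
  polymorphic markers: 51 / 53 (96.2%)
  Shannon index (presence-frequency): 3.807
Barcoding-gap analysis (Whittaker dissimilarities)
  intra-specific: n = 18, range 0.000 - 0.143
  inter-specific: n = 48, range 0.722 - 0.833
  overlap: 0.00% of observations in [min inter, max intra]
  PCA: PC1 46.85%, PC2 43.14% of total variance
  cophenetic correlation: r = 0.998
  between-region Mantel: r = 0.959, p = 0.001
```

Reading: of the 96 simulated CE runs one contained an out-of-scale peak and
was excluded; the surviving replicates consolidate into 53 binned markers
across 12 accessions, 96% of them polymorphic. Within-species (intra)
Whittaker dissimilarities stay below 0.15 while between-species (inter)
values start at 0.72 — a clean barcoding gap (0% overlap), so the NJ tree
recovers every species as a clade, the tree fits the distance matrix at
r = 0.998, and the two intron regions tell a concordant story (Mantel
r = 0.96, p = 0.001). `report$counts` gives the per-accession peak counts
per intron region and their sum; `report$tree` is an `ape::phylo` with
bootstrap node labels, ready for `writeTbpTree()`.

The same pipeline is scriptable from a shell via the installed CLI
(`system.file("cli", "tbp.R", package = "tbptools")`) with subcommands
`simulate`, `ingest`, `filter`, `consolidate`, `bin`, `diversity`, `gap`,
`pca`, `tree`, `mantel`, `insilico`, `report`, each reading its
predecessor's CSV/JSON/newick files.

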