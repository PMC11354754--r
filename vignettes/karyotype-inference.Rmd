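---
title: "Coverage-based karyotype inference: models, parameters, and design choices"
author: "KaryoDepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based karyotype inference: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KaryoDepth)
```

KaryoDepth infers fungal karyotypes from two independent signals — the
telomere/rDNA structure of an assembly and the binned sequencing depth of a
strain mapped against it — and couples them to a meiotic
chromosome-allocation simulator that predicts what offspring cohorts of an
aneuploid parent should look like. This vignette is the package's own
account of the models behind each stage, the tunable parameters and why
their defaults are what they are, and the places where the design was
genuinely open.

## Chromosome accounting from assembly structure

A contig is counted as a complete chromosome when it carries terminal
telomere repeat arrays — tandem copies of the 7 bp unit `TTAGGGG`
(equivalently `CCCCTAA` on the reverse strand) — at both ends. In this
clade the rDNA array can occupy a chromosome end, so a contig with a single
telomere plus a terminal rDNA array is also complete. Because the field
itself uses both conventions, `accountChromosomes()` reports two counts:

* `chromosome_count_strict` — double-sided-telomere contigs only;
* `chromosome_count_extended` — strict plus single-telomere contigs
  completed by a terminal rDNA array.

The extended count is the headline number (it is the rule under which a
fifteen-chromosome karyotype is recognized for the reference assembly);
the strict count is retained because contig tallies for less complete
assemblies are conventionally quoted that way.

### Telomere scanning

`scanTelomeres()` finds maximal tandem arrays by chaining exact matches of
the repeat unit and tolerating short mismatched stretches inside the chain.
Parameters, with defaults:

* `minCopies = 5` (copies): fewer than five tandem copies of a 7-mer can
  occur by chance in megabase-scale sequence and would not be called a
  telomere by eye either.
* `endWindow = 1000` (bp): an array must start (left) or end (right)
  within this distance of a contig end to count as terminal. Arrays
  elsewhere are reported as `interstitial` and excluded from accounting.
* `maxMismatchFraction = 0.1`: the fraction of the array span allowed to be
  uncovered by exact unit matches. This is implemented at the array level
  (chaining across gaps) rather than per unit, because a 7 bp unit admits
  no integer mismatch allowance below 1/7 — a per-unit rule would make the
  parameter dead at any realistic setting.

No published value exists for any of these three; they are documented
defaults, not inferred intent. Side assignment at both-ends-in-window
degeneracy (very short contigs) goes to the nearer end. Copy count is
`span / 7` rounded, so an array with an internal substitution still counts
its true copy number. Contigs with more than two terminal arrays — a
misassembly signature — are flagged (`multiTelomereFlag`) but never
"fixed".

### rDNA detection

`detectRdna()` is a seeded local-similarity search, equivalent in role to a
BLAST of rRNA references against the assembly but self-contained: exact
31-mer seeds (every 16 bp of the reference, both strands) locate candidate
regions, which are scored by affine-gap local alignment
(match +1, mismatch −1, gap open 10, extend 0.5) and merged when
overlapping. Defaults `minIdentity = 80`%, `minMatchLength = 500` bp are
permissive enough to catch cross-species rRNA similarity while rejecting
chance k-mer clustering. The package bundles a fixed synthetic rRNA-like
2.5 kb unit (`rdnaUnit()`) so fixtures need no downloads; any real rRNA
FASTA is accepted wherever a reference is taken.

## Binned depth and robust per-chromosome summaries

Depth is computed per 10 kb bin (`binSize = 10000` bp, the conventional
window for genome-scale depth plots) as aligned-bases-overlapping-bin /
bin-width, from coordinate-sorted BAM via `computeBins()` (primary,
non-duplicate, non-secondary records; `mapqMin = 0` by default, matching
default-parameter mapping practice) or from a depth table
(`readDepthTable()`, which also speaks the `sambamba depth window`
dialect).

Real binned coverage shows sporadic repeat-driven spikes and dips, so
`summarizeChromosomeDepth()` summarizes robustly:

1. short terminal bins (width < nominal) are excluded;
2. bins farther than `madK = 5` MADs from the chromosome median are masked
   (their fraction is reported — a useful assembly-quality signal);
3. the robust depth is the two-sided trimmed mean, `trimFraction = 0.1`
   per tail.

Trimming and masking overlap deliberately: masking catches extreme
outliers that would survive a 10% trim on long chromosomes, trimming
catches moderate ones below the MAD cutoff. A noiseless chromosome (MAD 0)
masks nothing. If every bin of a chromosome is masked the function errors
rather than returning a fabricated summary.

## Fold estimation and grid classification

The baseline is the median of per-chromosome robust depths
(`baselineMethod = "median"`; a kernel-density mode is available as an
option). The median is the right default because duplicated chromosomes
are a minority of the karyotype — in the strains this package models, at
most 2 of 15 chromosomes deviate, so the median sits firmly in the euploid
mass. When many chromosomes deviate at once the median biases folds
downward; the mode option and the reported raw folds are the escape hatch.

Raw folds `d_c / b` are classified onto the grid
`{1, 1.5, 2, 2.5, 3, 3.5, 4}` — the union of multiples observed across
strains (1.5, 2, 3, 4), plus 1 and the midpoints 2.5/3.5 so intermediate
states are representable instead of being forced onto a neighbor. A fold
is assigned to the nearest grid value only when the relative deviation is
within `tolerance = 0.12`; otherwise the chromosome is *unassigned*.
Published analyses of this kind read folds off depth plots by eye; the
tolerance makes that judgment reproducible. 0.12 splits the difference
between the tightest grid spacing (1 → 1.5 is ±20% around 1.25) and
typical fold noise at 50× with a few hundred bins per chromosome.

Verdict rule (a deliberate precedence, since the three conditions can
overlap): **ambiguous** if any chromosome is unassigned, else
**aneuploid** if any assigned multiple exceeds 1, else **euploid**.
Ambiguity is an explicit outcome, never silently rounded.

Assignment confidence is the agreement fraction over `bootstrapReps = 200`
bin-level resamples of the entire pipeline (robust depth → baseline →
fold → assignment), seeded. It is a stability measure, not a posterior
probability.

## Nuclear composition

A depth fold constrains only the *total* copy number per cell:
`multiple × nucleusCount` with a baseline of one copy per nucleus.
`inferNuclearComposition()` enumerates all unordered splits of that total
across nuclei with at least one copy each (complete enumeration, checked
against brute force in the tests), ordered by parsimony: fewest distinct
nucleus genotypes, then smallest maximum copy number. Parsimony ordering
is a package convention — the data cannot rank compositions.

Non-integer totals (a 1.5× fold in a nominally single-nucleus strain) are
unreachable by any fixed nucleus set. With `allowMixture = TRUE` they are
represented as a weighted two-component mixture of cell sub-populations
whose totals bracket the target — e.g. half the cells carrying one copy
and half carrying two. This is a representational device for
protoplast-derived strains that may carry more than one nucleus of the
same mating type, not a mechanistic claim. Folds below 1 (chromosome loss)
are reported as infeasible: the model deliberately does not represent
losses, mirroring the viability argument below.

## The meiosis model

Published reasoning about aneuploid offspring is at nucleus level; to give
it a simulable form the package adopts a chromatid-allocation abstraction:

1. `karyogamy()` sums the two parental nuclei (element-wise).
2. Each chromosome replicates: `2 K_c` chromatids.
3. `meiose()` distributes them over 4 spores. *Faithful*: each spore takes
   `floor(2K_c/4)`, the remainder goes to a uniformly random subset (so a
   trisomic chromosome's six chromatids split 2,2,1,1 — two disomic and
   two monosomic spores). *Disordered*: after the faithful allocation,
   each chromosome independently suffers a nondisjunction with probability
   `pNd`, moving one chromatid from a random donor spore to a random
   other spore.
4. Spores lacking any chromosome are inviable ("death through chromosome
   loss"); `simulateOffspring()` samples one uniformly chosen viable spore
   per meiosis, i.i.d. — offspring are independent single-spore isolates,
   not constrained tetrads.

This abstraction was chosen because it reproduces the two-class,
50:50 offspring prediction for a euploid + chr15-disomic dikaryon exactly,
gives `pNd` a concrete mechanistic meaning, and keeps chromatid
conservation (`sum over spores = 2 K_c`) as a checkable invariant. There
is no recombination, no chiasma placement, no mating-type genetics. The
orientation of trisomy resolution is uniform-random. Whether a 3× parent
strain carries (3,3) nuclei or an unequal split is not inferable from
depth data; the simulator takes the parental nuclei as input rather than
guessing.

`compareCohorts()` quantifies cohort consistency: exact binomial for two
classes, chi-square when all expected counts are ≥ 5, exact multinomial
enumeration otherwise; observed classes with zero predicted frequency give
p = 0 (reported as a degenerate fit).

## The synthetic-data generator

The generator defines the package's study conditions and is first-class,
tested code:

* `generateAssembly()` plants `CCCCTAA`/`TTAGGGG` arrays flush with contig
  ends and tandem rDNA units at planned offsets in i.i.d. background
  sequence at a GC target (default 0.52); every planted feature is
  recorded with 0-based half-open coordinates, making the truth table an
  exact oracle for the scanners.
* `simulateDepth()` draws bin depths from a negative binomial with mean
  `baseDepth × (nucleus-weighted copy number)` and variance
  `μ + dispersion·μ²`. Defaults: `baseDepth = 50`× per copy,
  `dispersion = 0.1`, with 2% of bins replaced by outliers scaled
  uniformly from [0.2, 5] to emulate repeat-driven fluctuations.
  `dispersion = 0` is the exact noiseless limit (bins equal their mean),
  which anchors the arithmetic tests. No published noise model exists for
  binned fungal coverage; the NB is a standard overdispersed stand-in and
  every parameter is configurable.
* `exampleStrain()` / `exampleCohort()` encode the strain configurations
  the package models, on a fifteen-chromosome karyotype with lengths
  descending 5.46 → 2.15 Mb. The twenty-offspring cohort is built to its
  printed tallies — 15 aneuploid / 5 euploid with ten strains at chr15
  fold 2 — which requires counting the three double-duplication offspring
  (chr14/chr13/chr11 mixture at 1.5× beside chr15 at 2×) among the ten;
  the enumerated single-duplication configurations in the source material
  overcount its own totals, and the printed tallies were taken as
  authoritative.

What the generator does *not* emulate: GC-coverage bias, mappability
structure, read-level errors, segmental (sub-chromosomal) CNVs, and
spatially correlated noise — real bins are not exchangeable within a
chromosome. Passing tests therefore demonstrate correctness of the
inference machinery under a clean overdispersed model, not robustness to
every artifact of real libraries; the MAD masking and trimmed means are
the hedge against the latter, and `mapqMin`/GC options exist for real
data.

## Reproducibility and problem sizes

Every stochastic entry point takes a seed, and one global seed fans out to
per-stage seeds through `deriveSeed()` (a fixed label hash folded into the
seed, always below 2³¹), so pipeline stages are independently
reproducible and identical configuration yields byte-identical artifacts —
`runPipeline()` records the seed and a config hash in `provenance.json`.

The test and acceptance workloads run at the study's native scale for
depth (fifteen chromosomes, ~57 Mb, ~5,700 bins of 10 kb per strain;
cohorts of 8 and 20 offspring) and at reduced contig lengths (60 kb) for
assembly-scan fixtures, where feature accounting is length-independent.
The recovery property uses 100 seeds at dispersion 0.2 — the upper end of
the modeled noise range — on a study-shaped karyotype with a duplicated
minority; meiosis analytics use 10⁴ offspring.

## Known limitations

* Whole-chromosome folds only; no sub-chromosomal CNV segmentation.
* Chromosome losses are treated as infeasible rather than modeled.
* The median baseline assumes duplicated chromosomes are a minority.
* The decision rule separating 1.5× from noisy 1×/2× is the package's
  tolerance parameter; no published rule exists.
* The three-telomere misassembly signature is flagged, not repaired.
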