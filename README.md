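# KaryoDepth

Coverage-based karyotype and aneuploidy inference for fungal genome
assemblies, with a seeded synthetic-data generator and a meiotic
chromosome-allocation simulator.

## The problem

Fungal chromosomes are too small to count under a microscope, so two
sequencing-based proxies are used instead:

1. **Chromosome accounting from assembly structure.** A contig carrying a
   terminal telomere repeat array — tandem copies of the 7 bp unit
   `(TTAGGGG)n`, or equivalently `(CCCCTAA)n` on the opposite strand — at
   *both* ends is a complete chromosome. In species where the rDNA array
   occupies a chromosome end, a contig with a single telomere and a terminal
   rDNA array is also complete. KaryoDepth scans assemblies for both
   feature types and reports a strict count (double-sided-telomere contigs,
   `n_ds`) and an extended count (`n_ds + n_single+rDNA`).

2. **Aneuploidy from binned sequencing depth.** Whole-chromosome
   duplications shift a chromosome's coverage relative to the genome
   baseline. With per-chromosome robust depth `d_c` (trimmed mean of 10 kb
   bins after MAD-based outlier masking) and baseline `b` (median of the
   `d_c`), the depth fold `f_c = d_c / b` is classified onto a discrete
   grid {1, 1.5, 2, 2.5, 3, 3.5, 4}: assign the nearest grid value `g` when
   `|f_c − g| / g ≤ tol` (default 0.12), otherwise leave the chromosome
   unassigned and call the strain *ambiguous*. A fold of 1.5 in a dikaryon
   means 3 total copies across 2 nuclei (one euploid and one duplicated
   nucleus); `inferNuclearComposition()` enumerates all per-nucleus integer
   splits compatible with the observed folds.

A third component models *why* offspring cohorts look the way they do:
`karyogamy()` + `meiose()` implement a replicate-then-distribute chromatid
allocation (each chromosome's `2·K_c` chromatids spread over 4 spores,
evenly in faithful mode, with per-chromosome nondisjunction probability
`p_nd` in disordered mode; spores missing any chromosome die). From a
dikaryon carrying one euploid and one chr15-disomic nucleus this predicts
exactly two viable offspring classes at frequency 0.5 each —
`compareCohorts()` tests observed cohort counts against such predictions.

Every stage is testable without external data: `generateAssembly()` plants
telomere/rDNA arrays at known coordinates, and `simulateDepth()` draws
binned coverage from a negative-binomial model (mean = base depth ×
nucleus-weighted copy number; dispersion 0 is the exact noiseless limit)
with sporadic repeat-driven outlier bins.

## Worked example

Simulate a homokaryotic strain with a duplicated accessory chromosome at
50× base depth and call its karyotype:

```r
library(KaryoDepth)

sim  <- simulateDepth(referenceChromosomeLengths(),
                      exampleStrain("L7", seed = 7))
call <- classifyFolds(sim$bins, strainId = "L7", seed = 7)
call
#> KaryotypeCall 'L7': aneuploid (baseline 49.1x)
#>   duplicated: chr15 at 2x

foldTable(call)[15, c("seqnames", "robustDepth", "rawFold", "multiple", "confidence")]
#>    seqnames robustDepth  rawFold multiple confidence
#> 15    chr15    101.5237 2.066693        2          1
```

chr15's robust depth (101.5×) is 2.07-fold the genome baseline (49.1×),
within the 12% tolerance of grid value 2, with bootstrap confidence 1: the
strain carries two copies of chr15. The nuclear composition consistent
with a 2× fold in a single-nucleus strain:

```r
inferNuclearComposition(call, nucleusCount = 1)[[1]]
#> NucleusMixture (1 nuclei/cell): 1 distinct genotype(s)
#>   w=1: chr15=2
```

Predict the offspring of a dikaryon with one euploid and one
chr15-duplicated nucleus, and test an observed cohort (3 aneuploid of 8)
against the prediction:

```r
eu <- setNames(rep(1L, 15), paste0("chr", 1:15))
an <- eu; an["chr15"] <- 2L
simulateOffspring(eu, an, nOffspring = 10000, seed = 1)
#> MeiosisCohort: 10000 viable offspring (faithful mode), 2 classes
#>   chr15:2                       5042  (0.504 +/- 0.005)
#>   euploid                       4958  (0.496 +/- 0.005)

compareCohorts(c(euploid = 0.5, "chr15:2" = 0.5),
               c(euploid = 5, "chr15:2" = 3))$pValue
#> [1] 0.7265625
```

The observed 3/8 split is fully consistent with the 50:50 prediction
(exact binomial, two-sided).

End-to-end runs (simulate → scan → call → meiosis → report) are driven by
`runPipeline()` or the wrapper script `inst/scripts/karyo-pipeline.R`.

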