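Package: KaryoDepth
Title: Coverage-Based Karyotype and Aneuploidy Inference for Fungal Assemblies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for chromosome-level karyotype inference in fungal genome
    assemblies. Detects terminal telomere repeat arrays and rDNA loci to
    classify contig completeness and predict chromosome number; computes
    binned sequencing depth from alignments or depth tables and summarizes
    it robustly per chromosome; estimates per-chromosome depth folds,
    classifies them onto a discrete copy-number grid, and calls strain-level
    aneuploidy; enumerates nuclear compositions compatible with observed
    folds in homokaryotic and heterokaryotic (dikaryotic) strains; and
    simulates karyogamy and meiotic chromosome allocation (faithful or with
    nondisjunction) to predict offspring ploidy-class distributions. A
    seeded synthetic-data generator produces assemblies with planted
    telomere and rDNA arrays, overdispersed binned coverage, and offspring
    cohorts with known truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    knitr
biocViews: CopyNumberVariation, Coverage, GenomeAssembly, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic-assembly.R'
    'assembly-scan.R'
    'synthetic-depth.R'
    'depth-profile.R'
    'meiosis-model.R'
    'ploidy-call.R'
    'pipeline.R'
    'utils.R'
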