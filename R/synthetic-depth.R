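#' @include AllClasses.R AllGenerics.R synthetic-assembly.R
NULL

#' Construct a StrainConfig
#'
#' @param strainId strain identifier.
#' @param copies per-chromosome copy numbers: a named vector (homokaryon), a
#'   matrix with one row per nucleus genotype, or a list of vectors.
#' @param weights mixture weights over nucleus genotypes (default equal).
#' @param baseDepth mean depth per chromosome copy (x coverage).
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 is the deterministic noiseless limit.
#' @param outlierFraction fraction of bins replaced by outliers emulating
#'   repeat-driven depth spikes/dips.
#' @param outlierRange range of the uniform outlier multiplier.
#' @param seed integer seed stored with the configuration.
#' @return a [StrainConfig-class].
#' @export
#' @examples
#' cv <- stats::setNames(rep(1, 15), paste0("chr", 1:15))
#' cv["chr15"] <- 2
#' strainConfig("L7", cv)
strainConfig <- function(strainId, copies, weights = NULL, baseDepth = 50,
                         dispersion = 0.1, outlierFraction = 0.02,
                         outlierRange = c(0.2, 5), seed = 1L) {
  if (is.list(copies) && !is.data.frame(copies))
    copies <- do.call(rbind, copies)
  if (is.null(dim(copies)))
    copies <- matrix(copies, nrow = 1L,
                     dimnames = list(NULL, names(copies)))
  storage.mode(copies) <- "integer"
  if (is.null(weights)) weights <- rep(1 / nrow(copies), nrow(copies))
  new("StrainConfig", strainId = as.character(strainId), copies = copies,
      weights = as.numeric(weights), baseDepth = as.numeric(baseDepth),
      dispersion = as.numeric(dispersion),
      outlierFraction = as.numeric(outlierFraction),
      outlierRange = as.numeric(outlierRange), seed = as.integer(seed))
}

#' Construct a DepthBins object
#'
#' @param x a GRanges with a `depth` metadata column, or a data.frame with
#'   columns `sequence`, `start` (0-based), `end`, `depth`.
#' @param binSize nominal bin width (bp).
#' @param source provenance label ("simulated", "alignments" or "table").
#' @return a [DepthBins-class].
#' @export
depthBins <- function(x, binSize, source = "table") {
  if (is.data.frame(x)) {
    gr <- GenomicRanges::GRanges(x$sequence,
                                 IRanges::IRanges(x$start + 1L, x$end))
    gr$depth <- as.numeric(x$depth)
    x <- gr
  }
  new("DepthBins", bins = x, binSize = as.integer(binSize),
      source = source)
}

.chromLengthsOf <- function(truth) {
  if (is(truth, "GenomeTruth")) return(chromLengths(truth))
  if (is.numeric(truth) && !is.null(names(truth))) {
    if (any(truth <= 0)) stop("zero-length chromosomes are not allowed")
    return(stats::setNames(as.integer(truth), names(truth)))
  }
  stop("'truth' must be a GenomeTruth or a named vector of lengths")
}

# align a strain's copy matrix with the genome's chromosome order
.alignCopies <- function(strain, lens) {
  cp <- strain@copies
  if (ncol(cp) != length(lens))
    stop("copy vector length (", ncol(cp), ") does not match chromosome ",
         "count (", length(lens), ")")
  if (!is.null(colnames(cp))) {
    if (!setequal(colnames(cp), names(lens)))
      stop("copy vector chromosome names do not match the genome")
    cp <- cp[, names(lens), drop = FALSE]
  } else colnames(cp) <- names(lens)
  cp
}

#' Simulate binned sequencing depth for a strain
#'
#' Draws per-bin depth from a negative-binomial model whose mean for a bin on
#' chromosome c is `baseDepth * weighted mean copy number of c` across the
#' strain's nuclei (variance `mu + dispersion * mu^2`; dispersion 0 returns
#' the mean exactly). A configured fraction of bins is then replaced by
#' outliers (depth scaled by a uniform draw from the outlier range),
#' emulating the sporadic repeat-driven depth fluctuations seen in real
#' binned coverage. Fully seeded and reproducible.
#'
#' @param truth a [GenomeTruth-class] or named vector of chromosome lengths.
#' @param strain a [StrainConfig-class].
#' @param binSize bin width (bp); default 10 kb.
#' @param seed integer seed (default: the strain's stored seed).
#' @return list with `bins` (a [DepthBins-class]) and `truth` (data.frame:
#'   `seqnames`, `weightedCopies`, `trueFold` where the fold baseline is the
#'   median weighted copy number over chromosomes).
#' @export
#' @examples
#' sim <- simulateDepth(referenceChromosomeLengths(),
#'                      exampleStrain("L7"), binSize = 10000)
#' sim$truth[15, ]
simulateDepth <- function(truth, strain, binSize = 10000,
                          seed = strain@seed) {
  stopifnot(is(strain, "StrainConfig"), binSize > 0)
  lens <- .chromLengthsOf(truth)
  cp <- .alignCopies(strain, lens)
  m <- drop(strain@weights %*% cp)
  bins <- GenomicRanges::tileGenome(lens, tilewidth = as.integer(binSize),
                                    cut.last.tile.in.chrom = TRUE)
  mu <- strain@baseDepth * m[as.character(GenomeInfoDb::seqnames(bins))]
  set.seed(deriveSeed(seed, paste0("depth/", strain@strainId)))
  if (strain@dispersion == 0) {
    depth <- mu
  } else {
    depth <- stats::rnbinom(length(mu), mu = mu, size = 1 / strain@dispersion)
  }
  if (strain@outlierFraction > 0) {
    out <- stats::runif(length(depth)) < strain@outlierFraction
    if (any(out))
      depth[out] <- depth[out] * stats::runif(sum(out),
                                              strain@outlierRange[1],
                                              strain@outlierRange[2])
  }
  bins$depth <- as.numeric(unname(depth))
  truthTab <- data.frame(seqnames = names(lens),
                         weightedCopies = unname(m),
                         trueFold = unname(m / stats::median(m)))
  list(bins = new("DepthBins", bins = bins, binSize = as.integer(binSize),
                  source = "simulated"),
       truth = truthTab)
}

#' Simulate read origins (and optionally sequences) for a strain
#'
#' Samples read start positions uniformly along chromosomes, with
#' per-chromosome sampling rates proportional to length x weighted copy
#' number, so duplicated chromosomes contribute proportionally more reads.
#' The origin table is sufficient to construct a truth alignment (e.g. a SAM
#' file) without running an external aligner.
#'
#' @inheritParams simulateDepth
#' @param nReads number of reads (0 gives a valid empty result).
#' @param readLength read length (bp); must be shorter than every chromosome.
#' @param sequences optional [Biostrings::DNAStringSet] matching `truth`;
#'   when supplied, read sequences are extracted (reverse-complemented for
#'   minus-strand reads).
#' @return list with `origins` (data.frame: `read`, `seqnames`, `start`
#'   0-based, `end`, `strand`) and `reads` (DNAStringSet or NULL).
#' @export
simulateReads <- function(truth, strain, nReads, readLength = 150,
                          seed = strain@seed, sequences = NULL) {
  lens <- .chromLengthsOf(truth)
  if (readLength >= min(lens))
    stop("readLength must be shorter than the shortest chromosome")
  cp <- .alignCopies(strain, lens)
  m <- drop(strain@weights %*% cp)
  set.seed(deriveSeed(seed, paste0("reads/", strain@strainId)))
  if (nReads == 0) {
    origins <- data.frame(read = character(), seqnames = character(),
                          start = integer(), end = integer(),
                          strand = character())
    return(list(origins = origins, reads = NULL))
  }
  prob <- as.numeric(lens) * m
  idx <- sample.int(length(lens), nReads, replace = TRUE,
                    prob = prob / sum(prob))
  start0 <- floor(stats::runif(nReads) * (lens[idx] - readLength + 1))
  origins <- data.frame(
    read = sprintf("read%07d", seq_len(nReads)),
    seqnames = names(lens)[idx],
    start = as.integer(start0),
    end = as.integer(start0 + readLength),
    strand = sample(c("+", "-"), nReads, replace = TRUE),
    stringsAsFactors = FALSE)
  reads <- NULL
  if (!is.null(sequences)) {
    reads <- Biostrings::DNAStringSet(lapply(seq_len(nReads), function(i) {
      s <- Biostrings::subseq(sequences[[origins$seqnames[i]]],
                              start = origins$start[i] + 1L,
                              width = readLength)
      if (origins$strand[i] == "-") Biostrings::reverseComplement(s) else s
    }))
    names(reads) <- origins$read
  }
  list(origins = origins, reads = reads)
}

#' Build a simulated offspring cohort with known truth
#'
#' Creates one [StrainConfig-class] per offspring (noise settings inherited
#' from the parent, seeds derived per strain), simulates its binned depth,
#' and records the truth labels used to validate the cohort screen.
#'
#' @param parent parental [StrainConfig-class]; its noise settings are
#'   shared by all offspring.
#' @param offspring named list of per-offspring copy specifications: a named
#'   copy vector, a matrix of nucleus genotypes, or a
#'   `list(copies =, weights =)` pair.
#' @param truth genome ([GenomeTruth-class] or named lengths) to simulate on.
#' @param binSize bin width (bp).
#' @param seed integer cohort seed.
#' @return a [CohortTruth-class] (includes per-offspring [DepthBins-class]).
#' @export
#' @examples
#' coh <- exampleCohort("L12", seed = 5)
#' table(cohortLabels(coh)$verdict)
buildCohort <- function(parent, offspring,
                        truth = referenceChromosomeLengths(),
                        binSize = 10000, seed = parent@seed) {
  stopifnot(is(parent, "StrainConfig"))
  if (length(offspring) == 0L) stop("cohort must contain >= 1 offspring")
  if (is.null(names(offspring)) || anyDuplicated(names(offspring)))
    stop("offspring must be uniquely named")
  configs <- vector("list", length(offspring))
  depths <- vector("list", length(offspring))
  labels <- vector("list", length(offspring))
  for (i in seq_along(offspring)) {
    id <- names(offspring)[i]
    spec <- offspring[[i]]
    if (is.list(spec) && !is.null(spec$copies)) {
      cpy <- spec$copies; w <- spec$weights
    } else { cpy <- spec; w <- NULL }
    cfg <- strainConfig(id, cpy, weights = w, baseDepth = parent@baseDepth,
                        dispersion = parent@dispersion,
                        outlierFraction = parent@outlierFraction,
                        outlierRange = parent@outlierRange,
                        seed = deriveSeed(seed, paste0("offspring/", id)))
    sim <- simulateDepth(truth, cfg, binSize = binSize)
    tf <- sim$truth
    dup <- tf[abs(tf$trueFold - 1) > 1e-9, , drop = FALSE]
    configs[[i]] <- cfg
    depths[[i]] <- sim$bins
    labels[[i]] <- data.frame(
      strainId = id,
      verdict = if (nrow(dup)) "aneuploid" else "euploid",
      duplicated = .dupString(dup$seqnames, dup$trueFold),
      stringsAsFactors = FALSE)
  }
  new("CohortTruth", parent = parent, configs = configs,
      labels = do.call(rbind, labels), depth = depths)
}

# 15-chromosome copy helpers -------------------------------------------------

.cv <- function(..., n = 15L) {
  v <- stats::setNames(rep(1L, n), paste0("chr", seq_len(n)))
  mods <- list(...)
  for (nm in names(mods)) v[nm] <- mods[[nm]]
  v
}

#' Strain configurations replicating the study strains
#'
#' Ready-made [StrainConfig-class] objects for the strains analyzed in the
#' study, on the fifteen-chromosome karyotype: `"L7"` (homokaryon, chr15
#' duplicated: fold 2), `"L2"`/`"L12"` (dikaryons carrying one euploid and
#' one chr15-duplicated nucleus: fold 1.5), `"L14"` (dikaryon with chr15 at
#' three copies in both nuclei: fold 3), `"Pr2C"` (protoplast strain modeled
#' as two same-mating-type nuclei differing in chr14: chr14 fold 1.5, chr15
#' fold 2), `"PrT"` (as Pr2C plus a chr1 mixture: chr1 1.5, chr14 1.5,
#' chr15 2), `"S10"`/`"S13"`/`"S15"` (offspring with a chr14/chr13/chr11
#' nucleus mixture at fold 1.5 plus chr15 at fold 2), and the euploid strains
#' `"L4"`, `"L11"`, `"L43"`.
#'
#' @param name strain name (see Details).
#' @param baseDepth,dispersion,outlierFraction,seed passed to
#'   [strainConfig()]; defaults are the study conditions (50x, NB dispersion
#'   0.1, 2 percent outlier bins).
#' @return a [StrainConfig-class].
#' @export
#' @examples
#' truthFolds(exampleStrain("Pr2C"))[c("chr14", "chr15")]
exampleStrain <- function(name, baseDepth = 50, dispersion = 0.1,
                          outlierFraction = 0.02, seed = 1L) {
  spec <- switch(name,
    L7 = list(copies = .cv(chr15 = 2L)),
    L2 = ,
    L12 = list(copies = rbind(.cv(), .cv(chr15 = 2L))),
    L14 = list(copies = rbind(.cv(chr15 = 3L), .cv(chr15 = 3L))),
    Pr2C = list(copies = rbind(.cv(chr15 = 2L),
                               .cv(chr14 = 2L, chr15 = 2L))),
    PrT = list(copies = rbind(.cv(chr15 = 2L),
                              .cv(chr1 = 2L, chr14 = 2L, chr15 = 2L))),
    S10 = list(copies = rbind(.cv(chr15 = 2L),
                              .cv(chr14 = 2L, chr15 = 2L))),
    S13 = list(copies = rbind(.cv(chr15 = 2L),
                              .cv(chr13 = 2L, chr15 = 2L))),
    S15 = list(copies = rbind(.cv(chr15 = 2L),
                              .cv(chr11 = 2L, chr15 = 2L))),
    L4 = ,
    L11 = ,
    L43 = list(copies = rbind(.cv(), .cv())),
    stop("unknown example strain: ", name)
  )
  strainConfig(name, spec$copies, baseDepth = baseDepth,
               dispersion = dispersion, outlierFraction = outlierFraction,
               seed = seed)
}

#' Offspring cohorts replicating the study's single-spore screens
#'
#' `exampleCohort("L12")` builds the eight-offspring cohort of strain L12:
#' three offspring with chr15 at two copies and five euploid.
#' `exampleCohort("L14")` builds the twenty-offspring cohort of strain L14:
#' ten offspring with chr15 at fold 2 (three of which — the S10/S13/S15
#' configurations — additionally carry a chr14, chr13 or chr11 nucleus
#' mixture at fold 1.5), four at fold 3, one at fold 4, and five euploid
#' (15 aneuploid in total).
#'
#' @param name "L12" or "L14".
#' @param truth genome to simulate on (default the reference karyotype).
#' @param binSize bin width (bp).
#' @param baseDepth,dispersion,outlierFraction study noise conditions.
#' @param seed integer cohort seed.
#' @return a [CohortTruth-class].
#' @export
exampleCohort <- function(name = c("L12", "L14"),
                          truth = referenceChromosomeLengths(),
                          binSize = 10000, baseDepth = 50, dispersion = 0.1,
                          outlierFraction = 0.02, seed = 1L) {
  name <- match.arg(name)
  parent <- exampleStrain(name, baseDepth = baseDepth,
                          dispersion = dispersion,
                          outlierFraction = outlierFraction, seed = seed)
  mix <- function(chrom) {
    m <- rbind(.cv(chr15 = 2L), .cv(chr15 = 2L))
    m[2L, chrom] <- 2L
    m
  }
  if (name == "L12") {
    off <- c(
      stats::setNames(replicate(3L, .cv(chr15 = 2L), simplify = FALSE),
                      paste0("L12_S", 1:3)),
      stats::setNames(replicate(5L, .cv(), simplify = FALSE),
                      paste0("L12_S", 4:8)))
  } else {
    off <- c(
      stats::setNames(replicate(7L, .cv(chr15 = 2L), simplify = FALSE),
                      paste0("L14_S0", 1:7)),
      list(L14_S10 = mix("chr14"), L14_S13 = mix("chr13"),
           L14_S15 = mix("chr11")),
      stats::setNames(replicate(4L, .cv(chr15 = 3L), simplify = FALSE),
                      paste0("L14_T", 1:4)),
      list(L14_Q1 = .cv(chr15 = 4L)),
      stats::setNames(replicate(5L, .cv(), simplify = FALSE),
                      paste0("L14_E", 1:5)))
  }
  buildCohort(parent, off, truth = truth, binSize = binSize, seed = seed)
}
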