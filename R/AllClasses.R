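#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges tileGenome binnedAverage mcols
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels Seqinfo
#' @importFrom IRanges IRanges
NULL

#' GenomeTruth: the plan for a synthetic assembly
#'
#' Describes a multi-contig genome with planted terminal telomere arrays and
#' tandem rDNA arrays, used by [generateAssembly()] and [simulateDepth()].
#' Coordinates are 0-based, half-open throughout.
#'
#' @slot chromLengths named integer vector of contig lengths (bp).
#' @slot telomerePlan data.frame with columns `contig`, `side` ("left" or
#'   "right") and `copies` (tandem copies of the 7 bp telomere unit).
#' @slot rdnaPlan data.frame with columns `contig`, `offset` (0-based bp),
#'   `unitLength` (bp) and `copies` (tandem copies of the rDNA unit).
#' @slot gcTarget numeric GC fraction for the random background, recycled
#'   over contigs.
#'
#' @seealso [genomeTruth()], [l7AssemblyPlan()], [pr2cAssemblyPlan()]
#' @export
setClass("GenomeTruth",
  representation(
    chromLengths = "integer",
    telomerePlan = "data.frame",
    rdnaPlan = "data.frame",
    gcTarget = "numeric"
  )
)

setValidity("GenomeTruth", function(object) {
  msg <- character()
  len <- object@chromLengths
  if (length(len) == 0L || any(is.na(len)) || any(len <= 0L))
    msg <- c(msg, "chromosome lengths must be positive")
  if (is.null(names(len)) || anyDuplicated(names(len)))
    msg <- c(msg, "chromosome lengths must have unique names")
  tp <- object@telomerePlan
  if (nrow(tp)) {
    if (!all(c("contig", "side", "copies") %in% names(tp)))
      msg <- c(msg, "telomerePlan needs columns contig, side, copies")
    else {
      if (!all(tp$contig %in% names(len)))
        msg <- c(msg, "telomerePlan references unknown contigs")
      if (!all(tp$side %in% c("left", "right")))
        msg <- c(msg, "telomerePlan side must be 'left' or 'right'")
      if (any(tp$copies < 1L))
        msg <- c(msg, "planted telomere copy count must be >= 1")
    }
  }
  rp <- object@rdnaPlan
  if (nrow(rp)) {
    if (!all(c("contig", "offset", "unitLength", "copies") %in% names(rp)))
      msg <- c(msg, "rdnaPlan needs columns contig, offset, unitLength, copies")
    else if (all(rp$contig %in% names(len))) {
      span <- rp$offset + rp$unitLength * rp$copies
      if (any(span > len[rp$contig]))
        msg <- c(msg, "rDNA array extends beyond contig length")
      if (any(rp$offset < 0))
        msg <- c(msg, "rDNA offset must be >= 0")
    } else msg <- c(msg, "rdnaPlan references unknown contigs")
  }
  if (any(object@gcTarget <= 0) || any(object@gcTarget >= 1))
    msg <- c(msg, "gcTarget must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' StrainConfig: a strain's nuclear composition and noise model
#'
#' Encodes the per-chromosome copy numbers of each nucleus type present in a
#' strain (a homokaryon has one row, a dikaryon two), the mixture weights,
#' and the parameters of the coverage noise model used by [simulateDepth()].
#'
#' @slot strainId single character strain identifier.
#' @slot copies integer matrix, one row per nucleus genotype, one column per
#'   chromosome; every entry >= 1.
#' @slot weights numeric mixture weights over nucleus genotypes, summing to 1.
#' @slot baseDepth numeric; mean sequencing depth contributed by a single
#'   chromosome copy (x coverage).
#' @slot dispersion negative-binomial overdispersion; 0 gives the noiseless
#'   deterministic limit.
#' @slot outlierFraction fraction of bins replaced by repeat-driven outliers.
#' @slot outlierRange length-2 numeric; outlier bins are scaled by a factor
#'   drawn uniformly from this range.
#' @slot seed integer seed used by the simulator.
#'
#' @seealso [strainConfig()], [simulateDepth()], [exampleStrain()]
#' @export
setClass("StrainConfig",
  representation(
    strainId = "character",
    copies = "matrix",
    weights = "numeric",
    baseDepth = "numeric",
    dispersion = "numeric",
    outlierFraction = "numeric",
    outlierRange = "numeric",
    seed = "integer"
  )
)

setValidity("StrainConfig", function(object) {
  msg <- character()
  if (length(object@strainId) != 1L) msg <- c(msg, "strainId must be length 1")
  cp <- object@copies
  if (!is.numeric(cp) || any(cp < 1) || any(cp != round(cp)))
    msg <- c(msg, "copy numbers must be integers >= 1")
  if (nrow(cp) != length(object@weights))
    msg <- c(msg, "one weight per nucleus genotype required")
  if (abs(sum(object@weights) - 1) > 1e-8 || any(object@weights < 0))
    msg <- c(msg, "weights must be non-negative and sum to 1")
  if (length(object@baseDepth) != 1L || object@baseDepth <= 0)
    msg <- c(msg, "baseDepth must be a single positive number")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@outlierFraction < 0 || object@outlierFraction > 1)
    msg <- c(msg, "outlierFraction must be in [0, 1]")
  if (length(object@outlierRange) != 2L || any(object@outlierRange <= 0) ||
      diff(object@outlierRange) < 0)
    msg <- c(msg, "outlierRange must be an increasing positive pair")
  if (length(msg)) msg else TRUE
})

#' DepthBins: binned sequencing depth along a genome
#'
#' A thin wrapper around a [GenomicRanges::GRanges] whose `depth` metadata
#' column holds the mean per-base coverage of each bin. Bins tile each
#' sequence without overlap; the last bin of a sequence may be short.
#'
#' @slot bins GRanges with a numeric `depth` metadata column.
#' @slot binSize integer nominal bin width (bp).
#' @slot source character; one of "simulated", "alignments", "table".
#'
#' @seealso [depthBins()], [computeBins()], [readDepthTable()],
#'   [summarizeChromosomeDepth()]
#' @export
setClass("DepthBins",
  representation(bins = "GRanges", binSize = "integer", source = "character")
)

setValidity("DepthBins", function(object) {
  msg <- character()
  gr <- object@bins
  if (!"depth" %in% names(GenomicRanges::mcols(gr)))
    msg <- c(msg, "bins must carry a 'depth' metadata column")
  else {
    d <- gr$depth
    if (any(is.na(d)) || any(d < 0)) msg <- c(msg, "depth must be >= 0")
  }
  if (object@binSize <= 0L) msg <- c(msg, "binSize must be positive")
  sq <- as.character(GenomeInfoDb::seqnames(gr))
  st <- BiocGenerics::start(gr)
  en <- BiocGenerics::end(gr)
  for (s in unique(sq)) {
    i <- which(sq == s)
    o <- order(st[i])
    a <- st[i][o]; b <- en[i][o]
    if (length(i) > 1L && any(a[-1L] != b[-length(b)] + 1L))
      msg <- c(msg, sprintf("bins on '%s' do not tile without gap/overlap", s))
  }
  if (length(msg)) msg else TRUE
})

#' KaryotypeCall: per-chromosome fold estimates and a strain verdict
#'
#' @slot strainId character strain identifier.
#' @slot folds data.frame with one row per chromosome: `seqnames`, `nBins`,
#'   `robustDepth`, `madDepth`, `maskedFraction`, `rawFold`, `multiple`
#'   (NA when unassigned) and `confidence` (bootstrap agreement fraction).
#' @slot baseline numeric baseline depth (x coverage) used for folds.
#' @slot grid numeric fold grid used for assignment.
#' @slot tolerance relative tolerance for grid assignment.
#' @slot verdict one of "euploid", "aneuploid", "ambiguous". Ambiguous (any
#'   chromosome unassigned) takes precedence over aneuploid.
#' @slot duplicated data.frame of duplicated chromosomes (`seqnames`,
#'   `multiple`), i.e. assigned multiples > 1.
#'
#' @seealso [classifyFolds()], [screenCohort()], [inferNuclearComposition()]
#' @export
setClass("KaryotypeCall",
  representation(
    strainId = "character",
    folds = "data.frame",
    baseline = "numeric",
    grid = "numeric",
    tolerance = "numeric",
    verdict = "character",
    duplicated = "data.frame"
  )
)

setValidity("KaryotypeCall", function(object) {
  msg <- character()
  if (!object@verdict %in% c("euploid", "aneuploid", "ambiguous"))
    msg <- c(msg, "verdict must be euploid, aneuploid or ambiguous")
  f <- object@folds
  need <- c("seqnames", "rawFold", "multiple", "confidence")
  if (!all(need %in% names(f)))
    msg <- c(msg, "folds is missing required columns")
  else {
    if (any(f$rawFold <= 0, na.rm = TRUE)) msg <- c(msg, "raw folds must be > 0")
    cf <- f$confidence[!is.na(f$confidence)]
    if (any(cf < 0 | cf > 1)) msg <- c(msg, "confidence must be in [0, 1]")
    un <- any(is.na(f$multiple))
    if (un && object@verdict != "ambiguous")
      msg <- c(msg, "unassigned folds require an ambiguous verdict")
    if (!un) {
      if (object@verdict == "euploid" && any(f$multiple != 1))
        msg <- c(msg, "euploid verdict requires all multiples equal to 1")
      if (object@verdict == "aneuploid" && !any(f$multiple > 1))
        msg <- c(msg, "aneuploid verdict requires a multiple > 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' NucleusMixture: a weighted set of nucleus genotypes
#'
#' Represents one candidate nuclear composition of a strain: each row of
#' `genotypes` is a per-chromosome integer copy vector of one nucleus
#' genotype, weighted by its share of the strain's nuclei. An infeasible
#' composition (fold unreachable with >= 1 copy per nucleus and no mixture
#' allowed) is returned with `feasible = FALSE`.
#'
#' @slot genotypes integer matrix, rows = distinct nucleus genotypes.
#' @slot weights numeric weights summing to 1 (when feasible).
#' @slot nucleusCount integer number of nuclei per cell assumed.
#' @slot feasible logical.
#' @slot note character; human-readable description.
#'
#' @seealso [inferNuclearComposition()]
#' @export
setClass("NucleusMixture",
  representation(
    genotypes = "matrix",
    weights = "numeric",
    nucleusCount = "integer",
    feasible = "logical",
    note = "character"
  )
)

setValidity("NucleusMixture", function(object) {
  msg <- character()
  if (object@feasible) {
    if (nrow(object@genotypes) != length(object@weights))
      msg <- c(msg, "one weight per genotype required")
    if (length(object@weights) &&
        (abs(sum(object@weights) - 1) > 1e-8 || any(object@weights < 0)))
      msg <- c(msg, "weights must be non-negative and sum to 1")
    if (length(object@genotypes) && any(object@genotypes < 1))
      msg <- c(msg, "every nucleus must carry >= 1 copy of every chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' CohortTruth: a simulated offspring cohort with known truth
#'
#' @slot parent the parental [StrainConfig-class].
#' @slot configs list of per-offspring [StrainConfig-class] objects.
#' @slot labels data.frame with one row per offspring: `strainId`, `verdict`
#'   (truth: "euploid"/"aneuploid"), `duplicated` (comma-separated
#'   "chrom:fold" entries, "" if none).
#' @slot depth list of per-offspring [DepthBins-class].
#'
#' @seealso [buildCohort()], [screenCohort()]
#' @export
setClass("CohortTruth",
  representation(
    parent = "StrainConfig",
    configs = "list",
    labels = "data.frame",
    depth = "list"
  )
)

setValidity("CohortTruth", function(object) {
  msg <- character()
  n <- length(object@configs)
  if (n == 0L) msg <- c(msg, "cohort must contain at least one offspring")
  if (nrow(object@labels) != n || length(object@depth) != n)
    msg <- c(msg, "labels/depth must match the number of offspring")
  if (length(msg)) msg else TRUE
})

#' SporeSet: the four products of one meiosis
#'
#' @slot spores 4 x n-chromosome integer matrix of per-spore copy numbers.
#' @slot viable logical(4); a spore is inviable iff it lacks any chromosome.
#'
#' @seealso [meiose()]
#' @export
setClass("SporeSet",
  representation(spores = "matrix", viable = "logical")
)

setValidity("SporeSet", function(object) {
  msg <- character()
  if (nrow(object@spores) != 4L) msg <- c(msg, "a meiosis yields 4 spores")
  if (length(object@viable) != 4L) msg <- c(msg, "4 viability flags required")
  if (any(object@spores < 0)) msg <- c(msg, "spore copies must be >= 0")
  if (!identical(unname(object@viable),
                 unname(apply(object@spores > 0, 1L, all))))
    msg <- c(msg, "viability flags inconsistent with zero-copy rule")
  if (length(msg)) msg else TRUE
})

#' MeiosisCohort: simulated offspring ploidy-class distribution
#'
#' @slot offspring integer matrix of sampled viable spore copy vectors.
#' @slot classes data.frame: `class` (copy-vector signature), `label`
#'   (human-readable duplication description), `count`, `frequency`,
#'   `se` (Monte-Carlo standard error).
#' @slot params list of simulation parameters (mode, pNd, n, seed).
#'
#' @seealso [simulateOffspring()], [compareCohorts()]
#' @export
setClass("MeiosisCohort",
  representation(offspring = "matrix", classes = "data.frame", params = "list")
)
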