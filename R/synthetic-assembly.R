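#' @include AllClasses.R AllGenerics.R
NULL

# the 7 bp telomere repeat units of this clade: C-rich unit at left
# (5') contig ends, its reverse complement at right ends
TELOMERE_UNIT_LEFT <- "CCCCTAA"
TELOMERE_UNIT_RIGHT <- "TTAGGGG"
.TELOMERE_UNIT_LENGTH <- 7L

#' The bundled synthetic rDNA repeat unit
#'
#' A fixed 2.5 kb synthetic rRNA-like sequence shipped with the package and
#' used as the default tandem-repeat unit for planted rDNA arrays and as the
#' default similarity-search reference, so no external rRNA download is
#' needed. Any real rRNA reference FASTA can be supplied instead wherever a
#' reference is accepted.
#'
#' @return a [Biostrings::DNAString] of length 2500.
#' @export
#' @examples
#' length(rdnaUnit())
rdnaUnit <- function() {
  path <- system.file("extdata", "rdna_unit_synthetic.fasta",
                      package = "KaryoDepth", mustWork = TRUE)
  Biostrings::readDNAStringSet(path)[[1L]]
}

#' Construct a GenomeTruth assembly plan
#'
#' @param chromLengths named numeric/integer vector of contig lengths (bp).
#' @param telomerePlan data.frame with columns `contig`, `side` ("left" or
#'   "right"), `copies`, and optionally `offset` (bp between the contig end
#'   and the array; default 0, i.e. the array is flush with the end).
#' @param rdnaPlan data.frame with columns `contig`, `offset` (0-based bp),
#'   `copies`, and optionally `unitLength` (default: length of [rdnaUnit()]).
#' @param gcTarget GC fraction of the random background (recycled).
#' @return a [GenomeTruth-class].
#' @export
#' @examples
#' gt <- genomeTruth(c(ctgA = 50000),
#'                   telomerePlan = data.frame(contig = "ctgA",
#'                                             side = c("left", "right"),
#'                                             copies = 10))
genomeTruth <- function(chromLengths,
                        telomerePlan = data.frame(),
                        rdnaPlan = data.frame(),
                        gcTarget = 0.52) {
  chromLengths <- stats::setNames(as.integer(chromLengths),
                                  names(chromLengths))
  if (nrow(telomerePlan)) {
    if (is.null(telomerePlan$offset)) telomerePlan$offset <- 0L
    telomerePlan$offset <- as.integer(telomerePlan$offset)
    telomerePlan$copies <- as.integer(telomerePlan$copies)
  }
  if (nrow(rdnaPlan)) {
    if (is.null(rdnaPlan$unitLength))
      rdnaPlan$unitLength <- length(rdnaUnit())
    rdnaPlan$offset <- as.integer(rdnaPlan$offset)
    rdnaPlan$unitLength <- as.integer(rdnaPlan$unitLength)
    rdnaPlan$copies <- as.integer(rdnaPlan$copies)
  }
  if (nrow(telomerePlan)) {
    span <- telomerePlan$offset + .TELOMERE_UNIT_LENGTH * telomerePlan$copies
    bad <- span > chromLengths[telomerePlan$contig]
    if (any(bad))
      stop("telomere plan exceeds contig length for: ",
           paste(unique(telomerePlan$contig[bad]), collapse = ", "))
  }
  new("GenomeTruth", chromLengths = chromLengths,
      telomerePlan = as.data.frame(telomerePlan),
      rdnaPlan = as.data.frame(rdnaPlan),
      gcTarget = rep_len(gcTarget, length(chromLengths)))
}

#' Chromosome lengths matching the fifteen-chromosome reference karyotype
#'
#' Fifteen lengths descending from 5.46 Mb to 2.15 Mb (the observed span of
#' the reference assembly's chromosomes), optionally scaled down for
#' desk-scale work. Chromosome 15, the accessory chromosome, is the
#' shortest.
#'
#' @param scale multiplicative length scale (1 = full size).
#' @return named integer vector `chr1` ... `chr15`.
#' @export
#' @examples
#' referenceChromosomeLengths(scale = 0.01)
referenceChromosomeLengths <- function(scale = 1) {
  mb <- c(5.46, 5.20, 4.95, 4.70, 4.45, 4.20, 4.11, 3.90, 3.65, 3.40,
          3.15, 2.90, 2.65, 2.40, 2.15)
  stats::setNames(as.integer(round(mb * 1e6 * scale)),
                  paste0("chr", seq_along(mb)))
}

#' Assembly plans replicating the study strains' contig structure
#'
#' `l7AssemblyPlan()` builds the fifteen-contig plan of the complete
#' reference assembly: 14 contigs with telomere arrays on both ends and one
#' contig with a single (left) telomere and a terminal rDNA array at the
#' right end. `pr2cAssemblyPlan()` builds the 16-contig plan observed for
#' strain Pr2C: 13 double-sided contigs, one single-telomere contig with
#' terminal rDNA, and two contigs with a single telomere only.
#' `prtAssemblyPlan()` builds a 17-contig plan like strain PrT: 11
#' double-sided contigs (the first carrying an extra terminal array, a
#' three-telomere misassembly signature), 5 single-telomere contigs and one
#' bare contig.
#'
#' @param contigLength length (bp) of every contig in the plan; desk-scale
#'   defaults keep scans fast while leaving room for terminal features.
#' @param telomereCopies tandem copies of the 7 bp unit per planted array.
#' @param rdnaCopies tandem copies of the rDNA unit per planted array.
#' @return a [GenomeTruth-class].
#' @export
#' @examples
#' l7AssemblyPlan()
l7AssemblyPlan <- function(contigLength = 60000, telomereCopies = 12,
                           rdnaCopies = 3) {
  lens <- stats::setNames(rep(contigLength, 15L), paste0("chr", 1:15))
  tp <- rbind(
    data.frame(contig = rep(paste0("chr", 1:14), each = 2L),
               side = rep(c("left", "right"), 14L),
               copies = telomereCopies),
    data.frame(contig = "chr15", side = "left", copies = telomereCopies)
  )
  unitLen <- length(rdnaUnit())
  rp <- data.frame(contig = "chr15",
                   offset = contigLength - unitLen * rdnaCopies,
                   unitLength = unitLen, copies = rdnaCopies)
  genomeTruth(lens, tp, rp)
}

#' @rdname l7AssemblyPlan
#' @export
pr2cAssemblyPlan <- function(contigLength = 60000, telomereCopies = 12,
                             rdnaCopies = 3) {
  lens <- stats::setNames(rep(contigLength, 16L), paste0("contig", 1:16))
  tp <- rbind(
    data.frame(contig = rep(paste0("contig", 1:13), each = 2L),
               side = rep(c("left", "right"), 13L),
               copies = telomereCopies),
    data.frame(contig = c("contig14", "contig15", "contig16"),
               side = "left", copies = telomereCopies)
  )
  unitLen <- length(rdnaUnit())
  rp <- data.frame(contig = "contig14",
                   offset = contigLength - unitLen * rdnaCopies,
                   unitLength = unitLen, copies = rdnaCopies)
  genomeTruth(lens, tp, rp)
}

#' @rdname l7AssemblyPlan
#' @export
prtAssemblyPlan <- function(contigLength = 60000, telomereCopies = 12) {
  lens <- stats::setNames(rep(contigLength, 17L), paste0("contig", 1:17))
  tp <- rbind(
    data.frame(contig = rep(paste0("contig", 1:11), each = 2L),
               side = rep(c("left", "right"), 11L),
               copies = telomereCopies, offset = 0L),
    # extra array near contig1's left end: a three-telomere misassembly
    data.frame(contig = "contig1", side = "left", copies = telomereCopies,
               offset = 300L),
    data.frame(contig = paste0("contig", 12:16), side = "left",
               copies = telomereCopies, offset = 0L)
  )
  genomeTruth(lens, tp)
}

#' Generate a synthetic assembly from a plan
#'
#' Builds one random sequence per contig at the plan's GC target, then plants
#' the planned features: `CCCCTAA` tandem arrays at left ends, `TTAGGGG`
#' arrays at right ends, and tandem copies of the rDNA unit at the planned
#' offsets. Identical plan + seed give a byte-identical result. The returned
#' truth table records every planted feature with 0-based half-open
#' coordinates and is the oracle for [scanTelomeres()] / [detectRdna()].
#'
#' @param truth a [GenomeTruth-class] plan.
#' @param seed integer seed.
#' @param unit rDNA repeat unit sequence (default the bundled [rdnaUnit()]).
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and
#'   `features` (data.frame: `contig`, `feature`, `side`, `start`, `end`,
#'   `copies`, `unit`).
#' @export
#' @examples
#' asm <- generateAssembly(l7AssemblyPlan(), seed = 42)
#' asm$sequences
#' table(asm$features$feature)
generateAssembly <- function(truth, seed, unit = rdnaUnit()) {
  stopifnot(is(truth, "GenomeTruth"))
  validObject(truth)
  rp <- truth@rdnaPlan
  if (nrow(rp) && any(rp$unitLength != length(unit)))
    stop("rDNA plan unitLength (", paste(unique(rp$unitLength), collapse = ","),
         ") does not match the supplied unit (", length(unit), " bp)")
  set.seed(deriveSeed(seed, "assembly"))
  lens <- truth@chromLengths
  tp <- truth@telomerePlan
  if (nrow(tp) && is.null(tp$offset)) tp$offset <- 0L
  unitChars <- strsplit(as.character(unit), "")[[1L]]
  seqs <- vector("list", length(lens))
  feats <- list()
  for (i in seq_along(lens)) {
    ctg <- names(lens)[i]
    L <- lens[[i]]
    gc <- truth@gcTarget[i]
    x <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    if (nrow(rp)) for (j in which(rp$contig == ctg)) {
      span <- rp$unitLength[j] * rp$copies[j]
      idx <- rp$offset[j] + seq_len(span)
      x[idx] <- rep(unitChars, rp$copies[j])
      feats[[length(feats) + 1L]] <- data.frame(
        contig = ctg, feature = "rdna", side = NA_character_,
        start = as.integer(rp$offset[j]),
        end = as.integer(rp$offset[j] + span),
        copies = rp$copies[j], unit = as.character(unit))
    }
    if (nrow(tp)) for (j in which(tp$contig == ctg)) {
      span <- .TELOMERE_UNIT_LENGTH * tp$copies[j]
      if (tp$side[j] == "left") {
        s <- tp$offset[j]
        u <- TELOMERE_UNIT_LEFT
      } else {
        s <- L - tp$offset[j] - span
        u <- TELOMERE_UNIT_RIGHT
      }
      x[s + seq_len(span)] <- rep(strsplit(u, "")[[1L]], tp$copies[j])
      feats[[length(feats) + 1L]] <- data.frame(
        contig = ctg, feature = "telomere", side = tp$side[j],
        start = as.integer(s), end = as.integer(s + span),
        copies = tp$copies[j], unit = u)
    }
    seqs[[i]] <- paste(x, collapse = "")
  }
  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequences) <- names(lens)
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(contig = character(), feature = character(),
               side = character(), start = integer(), end = integer(),
               copies = integer(), unit = character())
  features <- features[order(features$contig, features$start), ]
  rownames(features) <- NULL
  list(sequences = sequences, features = features)
}
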