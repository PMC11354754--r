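#' @include AllClasses.R AllGenerics.R synthetic-assembly.R
NULL

.asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(list(x)))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop("expected a DNAStringSet, DNAString, FASTA path or character vector")
}

# collapse motifs that are reverse complements of each other
.canonicalMotifs <- function(motifs) {
  canon <- vapply(motifs, function(m) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    min(m, rc)
  }, character(1))
  motifs[!duplicated(canon)]
}

# chain exact unit matches (1-based starts) into maximal tandem arrays,
# tolerating uncovered (mismatched) stretches up to maxFrac of the span
.chainUnits <- function(starts, unitLen, maxFrac) {
  if (!length(starts)) return(NULL)
  starts <- sort(starts)
  keep <- logical(length(starts))
  last <- -Inf
  for (i in seq_along(starts)) {            # drop overlapping matches
    if (starts[i] >= last + unitLen) { keep[i] <- TRUE; last <- starts[i] }
  }
  starts <- starts[keep]
  out <- list()
  aStart <- starts[1L]; aEnd <- starts[1L] + unitLen - 1L; uncov <- 0L
  for (s in starts[-1L]) {
    g <- s - aEnd - 1L
    newSpan <- s + unitLen - 1L - aStart + 1L
    ok <- g == 0L ||
      (g <= 3L * unitLen && (uncov + g) / newSpan <= maxFrac)
    if (ok) {
      uncov <- uncov + g
      aEnd <- s + unitLen - 1L
    } else {
      out[[length(out) + 1L]] <- c(aStart, aEnd)
      aStart <- s; aEnd <- s + unitLen - 1L; uncov <- 0L
    }
  }
  out[[length(out) + 1L]] <- c(aStart, aEnd)
  do.call(rbind, out)
}

#' Scan sequences for terminal telomere repeat arrays
#'
#' Reports maximal tandem arrays of the telomere unit (and of its reverse
#' complement, so scanning either `TTAGGGG` or `CCCCTAA` finds both
#' orientations). An array is a chain of exact unit matches; short
#' mismatched stretches inside the chain are tolerated as long as they make
#' up at most `maxMismatchFraction` of the array span. Arrays whose start
#' (left) or end (right) lies within `endWindow` of a contig end are
#' assigned that side; arrays elsewhere are reported with side
#' `"interstitial"` and are excluded from chromosome accounting.
#'
#' @param sequences a [Biostrings::DNAStringSet] (or DNAString / FASTA path).
#' @param motifs telomere repeat unit(s); reverse-complement duplicates are
#'   collapsed. Default `TTAGGGG` (equivalently `CCCCTAA`).
#' @param minCopies minimum tandem copies for a reported array.
#' @param endWindow distance (bp) from a contig end within which an array
#'   counts as terminal.
#' @param maxMismatchFraction maximum fraction of mismatching bases tolerated
#'   inside an array.
#' @return data.frame of telomere hits: `contig`, `side` ("left", "right" or
#'   "interstitial"), `start`/`end` (0-based half-open), `unit` (the unit as
#'   it appears on the forward strand), `copies`, `strand` ("+" when the
#'   G-rich unit is on the forward strand).
#' @export
#' @examples
#' asm <- generateAssembly(l7AssemblyPlan(), seed = 42)
#' head(scanTelomeres(asm$sequences))
scanTelomeres <- function(sequences, motifs = TELOMERE_UNIT_RIGHT,
                          minCopies = 5, endWindow = 1000,
                          maxMismatchFraction = 0.1) {
  sequences <- .asDNAStringSet(sequences)
  if (length(sequences) == 0L) stop("no sequences supplied")
  if (length(motifs) == 0L) stop("no motifs supplied")
  motifs <- .canonicalMotifs(motifs)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  hits <- list()
  for (i in seq_along(sequences)) {
    subject <- sequences[[i]]
    L <- length(subject)
    freq <- Biostrings::alphabetFrequency(subject)
    nonACGT <- sum(freq) - sum(freq[c("A", "C", "G", "T")])
    if (nonACGT > 0)
      warning(sprintf("%s: %d non-ACGT position(s) skipped",
                      names(sequences)[i], nonACGT))
    for (m in motifs) {
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(m)))
      units <- unique(c(m, rc))
      for (u in units) {
        unitLen <- nchar(u)
        st <- BiocGenerics::start(Biostrings::matchPattern(u, subject))
        arr <- .chainUnits(st, unitLen, maxMismatchFraction)
        if (is.null(arr)) next
        for (k in seq_len(nrow(arr))) {
          s1 <- arr[k, 1L]; e1 <- arr[k, 2L]
          copies <- as.integer(round((e1 - s1 + 1L) / unitLen))
          if (copies < minCopies) next
          distL <- s1 - 1L
          distR <- L - e1
          side <- if (distL <= endWindow && distR <= endWindow) {
            if (distL <= distR) "left" else "right"
          } else if (distL <= endWindow) "left"
          else if (distR <= endWindow) "right"
          else "interstitial"
          hits[[length(hits) + 1L]] <- data.frame(
            contig = names(sequences)[i], side = side,
            start = s1 - 1L, end = e1, unit = u, copies = copies,
            strand = if (u == m) "+" else "-",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(contig = character(), side = character(),
                      start = integer(), end = integer(), unit = character(),
                      copies = integer(), strand = character()))
  out <- do.call(rbind, hits)
  out <- out[order(out$contig, out$start), ]
  rownames(out) <- NULL
  out
}

#' Detect rDNA loci by seeded local similarity search
#'
#' Finds regions of each contig similar to the supplied rRNA reference
#' sequence(s). Candidate regions are located by exact k-mer seed matches
#' (both strands), merged into loci, and scored by affine-gap local
#' alignment of the reference against the candidate region; loci with
#' percent identity below `minIdentity` or span below `minMatchLength` are
#' dropped, and overlapping loci are merged. A locus is flagged terminal
#' when it lies within `endWindow` of either contig end.
#'
#' @param sequences a [Biostrings::DNAStringSet] (or DNAString / FASTA path).
#' @param references rRNA reference sequence(s): DNAStringSet, DNAString or
#'   FASTA path. Default: the bundled synthetic [rdnaUnit()].
#' @param minIdentity minimum percent identity (0-100).
#' @param minMatchLength minimum locus span (bp).
#' @param endWindow terminal-flag window (bp).
#' @param seedLength,seedStep exact-seed width and spacing (bp).
#' @return data.frame of rDNA loci: `contig`, `start`/`end` (0-based
#'   half-open), `reference`, `identity` (percent), `strand`, `terminal`,
#'   `side` ("left"/"right" when terminal, NA otherwise).
#' @export
detectRdna <- function(sequences, references = NULL, minIdentity = 80,
                       minMatchLength = 500, endWindow = 1000,
                       seedLength = 31, seedStep = 16) {
  sequences <- .asDNAStringSet(sequences)
  if (is.null(references))
    references <- Biostrings::DNAStringSet(list(rdna_unit = rdnaUnit()))
  references <- .asDNAStringSet(references)
  if (length(references) == 0L) stop("no reference sequences supplied")
  if (any(Biostrings::width(references) == 0L))
    stop("empty reference sequence")
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  seedLength <- as.integer(seedLength)
  seedStep <- as.integer(seedStep)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  loci <- list()
  for (r in seq_along(references)) {
    for (strand in c("+", "-")) {
      ref <- references[[r]]
      if (strand == "-") ref <- Biostrings::reverseComplement(ref)
      rl <- length(ref)
      if (rl < seedLength) stop("reference shorter than seedLength")
      pos <- unique(c(seq(1L, rl - seedLength + 1L, by = seedStep),
                      rl - seedLength + 1L))
      seeds <- Biostrings::DNAStringSet(ref, start = pos, width = seedLength)
      pd <- Biostrings::PDict(seeds)
      for (i in seq_along(sequences)) {
        subject <- sequences[[i]]
        mh <- Biostrings::matchPDict(pd, subject)
        st <- unlist(lapply(mh, BiocGenerics::start))
        if (!length(st)) next
        en <- st + seedLength - 1L
        o <- order(st); st <- st[o]; en <- en[o]
        # cluster seed hits separated by less than one reference length
        brk <- c(TRUE, st[-1L] - cummax(en)[-length(en)] > rl)
        cl <- cumsum(brk)
        for (g in unique(cl)) {
          hullS <- min(st[cl == g]); hullE <- max(en[cl == g])
          if (hullE - hullS + 1L < minMatchLength) next
          regS <- max(1L, hullS - rl)
          regE <- min(length(subject), hullE + rl)
          aln <- Biostrings::pairwiseAlignment(
            ref, Biostrings::subseq(subject, regS, regE),
            type = "local", substitutionMatrix = submat,
            gapOpening = 10, gapExtension = 0.5)
          ident <- Biostrings::pid(aln)
          if (ident < minIdentity) next
          loci[[length(loci) + 1L]] <- data.frame(
            contig = names(sequences)[i], start = hullS - 1L, end = hullE,
            reference = names(references)[r], identity = ident,
            strand = strand, contigLength = length(subject),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), reference = character(),
                      identity = numeric(), strand = character(),
                      terminal = logical(), side = character())
  if (!length(loci)) return(empty)
  out <- do.call(rbind, loci)
  # merge overlapping loci per contig, keeping the best identity
  merged <- list()
  for (ctg in unique(out$contig)) {
    x <- out[out$contig == ctg, ]
    x <- x[order(x$start), ]
    cur <- x[1L, ]
    flush <- function(cur) { merged[[length(merged) + 1L]] <<- cur }
    for (k in seq_len(nrow(x))[-1L]) {
      if (x$start[k] < cur$end) {
        cur$end <- max(cur$end, x$end[k])
        cur$start <- min(cur$start, x$start[k])
        if (x$identity[k] > cur$identity) {
          cur$identity <- x$identity[k]
          cur$reference <- x$reference[k]
          cur$strand <- x$strand[k]
        }
      } else { flush(cur); cur <- x[k, ] }
    }
    flush(cur)
  }
  out <- do.call(rbind, merged)
  L <- out$contigLength
  distL <- out$start
  distR <- L - out$end
  out$terminal <- distL <= endWindow | distR <= endWindow
  out$side <- ifelse(!out$terminal, NA_character_,
                     ifelse(distL <= distR, "left", "right"))
  out$contigLength <- NULL
  out <- out[out$end - out$start >= minMatchLength, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate contigs with telomere and rDNA completeness classes
#'
#' Combines telomere hits and rDNA loci into a per-contig annotation:
#' telomere class `double` (terminal arrays on both ends), `single`
#' (one end) or `none`, and completeness class `complete_two_telomeres`,
#' `complete_telomere_plus_rdna` (exactly one telomere side plus a terminal
#' rDNA locus on the opposite end) or `partial`. Contigs with more than two
#' terminal telomere arrays (a misassembly signature) are flagged.
#'
#' @param telomeres telomere hit table from [scanTelomeres()].
#' @param rdna rDNA locus table from [detectRdna()] (may be empty).
#' @param contigLengths named vector of contig lengths; every contig to be
#'   annotated must be present.
#' @return data.frame with one row per contig: `contig`, `length`,
#'   `telomereClass`, `nTerminalArrays`, `multiTelomereFlag`, `nRdna`,
#'   `terminalRdnaSides`, `completeness`.
#' @export
annotateContigs <- function(telomeres, rdna = NULL, contigLengths) {
  if (is.null(names(contigLengths)) || anyDuplicated(names(contigLengths)))
    stop("contigLengths must be uniquely named")
  if (is.null(rdna))
    rdna <- data.frame(contig = character(), terminal = logical(),
                       side = character())
  rows <- lapply(names(contigLengths), function(ctg) {
    th <- telomeres[telomeres$contig == ctg &
                    telomeres$side %in% c("left", "right"), , drop = FALSE]
    sides <- unique(th$side)
    telClass <- if (all(c("left", "right") %in% sides)) "double"
      else if (length(sides) == 1L) "single" else "none"
    rd <- rdna[rdna$contig == ctg, , drop = FALSE]
    termSides <- unique(rd$side[rd$terminal %in% TRUE])
    completeness <- if (telClass == "double") "complete_two_telomeres"
      else if (telClass == "single" &&
               any(setdiff(c("left", "right"), sides) %in% termSides))
        "complete_telomere_plus_rdna"
      else "partial"
    data.frame(contig = ctg, length = unname(contigLengths[ctg]),
               telomereClass = telClass, nTerminalArrays = nrow(th),
               multiTelomereFlag = nrow(th) > 2L, nRdna = nrow(rd),
               terminalRdnaSides = paste(termSides, collapse = ","),
               completeness = completeness, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chromosome accounting from contig annotations
#'
#' Tallies contigs per completeness class and derives two chromosome counts:
#' the strict count (double-sided-telomere contigs only) and the extended
#' count (double-sided contigs plus single-telomere contigs completed by a
#' terminal rDNA array — the rule under which the reference assembly is
#' counted as fifteen chromosomes).
#'
#' @param annotations per-contig annotation table from [annotateContigs()].
#' @return list with `n_double_sided`, `n_single_plus_rdna`, `n_single_only`,
#'   `n_none`, `chromosome_count_strict`, `chromosome_count_extended` and
#'   `n_contigs`.
#' @export
#' @examples
#' asm <- generateAssembly(l7AssemblyPlan(), seed = 42)
#' tel <- scanTelomeres(asm$sequences)
#' rd <- detectRdna(asm$sequences)
#' ann <- annotateContigs(tel, rd, Biostrings::width(asm$sequences) |>
#'                          stats::setNames(names(asm$sequences)))
#' accountChromosomes(ann)
accountChromosomes <- function(annotations) {
  if (anyDuplicated(annotations$contig))
    stop("duplicate contig ids in annotations")
  nDouble <- sum(annotations$completeness == "complete_two_telomeres")
  nSingleRdna <- sum(annotations$completeness == "complete_telomere_plus_rdna")
  nSingleOnly <- sum(annotations$telomereClass == "single" &
                     annotations$completeness == "partial")
  nNone <- sum(annotations$telomereClass == "none")
  list(
    n_double_sided = nDouble,
    n_single_plus_rdna = nSingleRdna,
    n_single_only = nSingleOnly,
    n_none = nNone,
    chromosome_count_strict = nDouble,
    chromosome_count_extended = nDouble + nSingleRdna,
    n_contigs = nrow(annotations)
  )
}

#' One-call assembly scan
#'
#' Runs [scanTelomeres()], [detectRdna()], [annotateContigs()] and
#' [accountChromosomes()] on an assembly.
#'
#' @param sequences assembly (DNAStringSet or FASTA path).
#' @param references rRNA reference(s); default the bundled [rdnaUnit()].
#' @param ... passed to [scanTelomeres()] and [detectRdna()] (shared
#'   arguments: `endWindow`).
#' @param minCopies,maxMismatchFraction telomere scan settings.
#' @param minIdentity,minMatchLength rDNA search settings.
#' @param endWindow terminal window shared by both scans.
#' @return list with `telomeres`, `rdna`, `annotations`, `accounting`.
#' @export
scanAssembly <- function(sequences, references = NULL, minCopies = 5,
                         endWindow = 1000, maxMismatchFraction = 0.1,
                         minIdentity = 80, minMatchLength = 500, ...) {
  sequences <- .asDNAStringSet(sequences)
  tel <- scanTelomeres(sequences, minCopies = minCopies,
                       endWindow = endWindow,
                       maxMismatchFraction = maxMismatchFraction)
  rd <- detectRdna(sequences, references = references,
                   minIdentity = minIdentity,
                   minMatchLength = minMatchLength, endWindow = endWindow)
  lens <- stats::setNames(Biostrings::width(sequences), names(sequences))
  ann <- annotateContigs(tel, rd, lens)
  list(telomeres = tel, rdna = rd, annotations = ann,
       accounting = accountChromosomes(ann))
}
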