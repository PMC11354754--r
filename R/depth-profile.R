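#' @include AllClasses.R AllGenerics.R synthetic-depth.R
NULL

#' Compute binned depth from a coordinate-sorted BAM file
#'
#' Depth of a bin is the sum of aligned bases overlapping the bin divided by
#' the bin width (mean per-base coverage), counting only primary,
#' non-duplicate, non-secondary, non-supplementary records with mapping
#' quality at least `mapqMin`.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param binSize bin width (bp); default 10 kb.
#' @param mapqMin minimum mapping quality (default 0: count everything
#'   primary).
#' @return a [DepthBins-class] with source `"alignments"`.
#' @export
computeBins <- function(bam, binSize = 10000, mapqMin = 0) {
  stopifnot(binSize > 0)
  bf <- Rsamtools::BamFile(bam)
  idx <- paste0(bam, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM file must be coordinate-sorted and indexed (missing .bai): ",
         bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  so <- hdr$text[["@HD"]]
  if (!is.null(so) && any(grepl("^SO:", so)) &&
      !any(so == "SO:coordinate"))
    stop("BAM file is not coordinate-sorted: ", bam)
  lens <- hdr$targets
  if (!length(lens)) stop("BAM header has no reference sequences")
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE),
    mapqFilter = as.integer(mapqMin))
  ga <- GenomicAlignments::readGAlignments(bf, param = param)
  if (length(ga) == 0L)
    warning("no alignments pass the filters; all bins are zero")
  cov <- GenomicAlignments::coverage(ga)
  bins <- GenomicRanges::tileGenome(lens, tilewidth = as.integer(binSize),
                                    cut.last.tile.in.chrom = TRUE)
  bins <- GenomicRanges::binnedAverage(bins, cov, "depth")
  new("DepthBins", bins = bins, binSize = as.integer(binSize),
      source = "alignments")
}

#' Read a per-bin depth table
#'
#' Ingests a depth table in either the package's own layout (`dialect =
#' "simple"`: tab-separated `sequence`, `start`, `end`, `depth` with 0-based
#' half-open coordinates) or the layout written by `sambamba depth window`
#' (`dialect = "sambamba"`: `# chrom  chromStart  chromEnd  readCount
#' meanCoverage ...`; `meanCoverage` is taken as the bin depth). Malformed
#' rows are reported with their line numbers; mixed bin sizes (other than a
#' short final bin per sequence) are rejected unless `allowRagged`.
#'
#' @param path path to the TSV file.
#' @param dialect "simple" or "sambamba".
#' @param allowRagged accept inconsistent bin widths.
#' @return a [DepthBins-class] with source `"table"`.
#' @export
readDepthTable <- function(path, dialect = c("simple", "sambamba"),
                           allowRagged = FALSE) {
  dialect <- match.arg(dialect)
  raw <- utils::read.delim(path, comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (dialect == "sambamba") {
    names(raw) <- sub("^#\\s*", "", names(raw))
    need <- c("chrom", "chromStart", "chromEnd", "meanCoverage")
    if (!all(need %in% names(raw)))
      stop("not a sambamba window-depth table; expected columns: ",
           paste(need, collapse = ", "))
    df <- data.frame(sequence = raw$chrom, start = raw$chromStart,
                     end = raw$chromEnd, depth = raw$meanCoverage,
                     stringsAsFactors = FALSE)
  } else {
    need <- c("sequence", "start", "end", "depth")
    if (!all(need %in% names(raw)))
      stop("expected columns: ", paste(need, collapse = ", "))
    df <- raw[need]
  }
  lineOf <- function(i) i + 1L   # header occupies line 1
  bad <- which(!is.finite(df$depth) | df$depth < 0)
  if (length(bad))
    stop("invalid depth at line ", paste(lineOf(bad), collapse = ", "),
         " of ", path)
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("empty or inverted bin at line ", paste(lineOf(bad), collapse = ", "))
  width <- df$end - df$start
  full <- max(width)
  if (!allowRagged) {
    lastBin <- !duplicated(df$sequence, fromLast = TRUE)
    bad <- which(width != full & !lastBin)
    if (length(bad))
      stop("inconsistent bin sizes at line ",
           paste(lineOf(bad), collapse = ", "),
           " (use allowRagged = TRUE to accept)")
  }
  depthBins(df, binSize = full, source = "table")
}

#' Write a DepthBins table
#'
#' Writes the tab-separated `sequence`, `start`, `end`, `depth` layout
#' (0-based half-open) read back by [readDepthTable()].
#'
#' @param bins a [DepthBins-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDepthTable <- function(bins, path) {
  stopifnot(is(bins, "DepthBins"))
  utils::write.table(as.data.frame(bins), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Robust per-chromosome depth summaries
#'
#' For each sequence: short terminal bins (width below the nominal bin size)
#' are excluded; bins farther than `madK` median absolute deviations from
#' the chromosome median are masked as outliers; the robust depth is the
#' two-sided trimmed mean (`trimFraction` per tail) of the remaining bins.
#'
#' @param bins a [DepthBins-class].
#' @param trimFraction trim per tail for the trimmed mean.
#' @param madK outlier cutoff in MADs from the chromosome median.
#' @return data.frame with one row per sequence: `seqnames`, `nBins` (full
#'   bins), `robustDepth`, `madDepth`, `maskedFraction`.
#' @export
#' @examples
#' sim <- simulateDepth(referenceChromosomeLengths(), exampleStrain("L7"))
#' head(summarizeChromosomeDepth(sim$bins))
summarizeChromosomeDepth <- function(bins, trimFraction = 0.1, madK = 5) {
  stopifnot(is(bins, "DepthBins"))
  df <- as.data.frame(bins)
  df$width <- df$end - df$start
  sqs <- intersect(GenomeInfoDb::seqlevels(bins@bins), unique(df$sequence))
  rows <- lapply(sqs, function(sq) {
    d <- df$depth[df$sequence == sq & df$width == bins@binSize]
    if (!length(d))
      stop("no full bins on sequence '", sq, "'")
    med <- stats::median(d)
    madv <- stats::mad(d)
    masked <- abs(d - med) > madK * madv
    if (all(masked))
      stop("all bins masked as outliers on sequence '", sq, "'")
    data.frame(seqnames = sq, nBins = length(d),
               robustDepth = mean(d[!masked], trim = trimFraction),
               madDepth = madv,
               maskedFraction = mean(masked),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot per-chromosome depth tracks
#'
#' A simple multi-panel line plot of binned depth along each chromosome,
#' with the genome-wide baseline (median of robust per-chromosome depths)
#' drawn for reference — the visual used to judge per-chromosome folds.
#'
#' @param bins a [DepthBins-class].
#' @param baseline optional baseline depth to draw; computed from
#'   [summarizeChromosomeDepth()] when NULL.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the baseline used.
#' @export
plotDepthBins <- function(bins, baseline = NULL, ...) {
  df <- as.data.frame(bins)
  if (is.null(baseline)) {
    cs <- summarizeChromosomeDepth(bins)
    baseline <- stats::median(cs$robustDepth)
  }
  sqs <- unique(df$sequence)
  nr <- ceiling(sqrt(length(sqs)))
  op <- graphics::par(mfrow = c(nr, ceiling(length(sqs) / nr)),
                      mar = c(2, 3, 2, 0.5))
  on.exit(graphics::par(op))
  ylim <- c(0, max(df$depth) * 1.05)
  for (sq in sqs) {
    x <- df[df$sequence == sq, ]
    graphics::plot((x$start + x$end) / 2e6, x$depth, type = "l",
                   main = sq, xlab = "Mb", ylab = "depth", ylim = ylim, ...)
    graphics::abline(h = baseline, col = "grey50", lty = 2)
    graphics::abline(h = baseline * c(1.5, 2, 3), col = "grey80", lty = 3)
  }
  invisible(baseline)
}
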