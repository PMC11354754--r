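# shared fixture builders (all generated in code; no stored binaries)

# per-chromosome copy vector on an n-chromosome karyotype
copyVec <- function(..., n = 15L) {
  v <- stats::setNames(rep(1L, n), paste0("chr", seq_len(n)))
  mods <- list(...)
  for (nm in names(mods)) v[nm] <- as.integer(mods[[nm]])
  v
}

smallLengths <- function(k = 4L, len = 2e6) {
  stats::setNames(rep(as.integer(len), k), paste0("chr", seq_len(k)))
}

# a minimal coordinate-sorted SAM -> indexed BAM; reads are perfect matches
samToBam <- function(targets, reads, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("bamfix")
    dir.create(dir)
  }
  hd <- c("@HD\tVN:1.6\tSO:coordinate",
          sprintf("@SQ\tSN:%s\tLN:%d", names(targets), targets))
  body <- character(0)
  if (nrow(reads)) {
    reads <- reads[order(match(reads$rname, names(targets)), reads$pos), ]
    body <- sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                    reads$qname, reads$rname, reads$pos, reads$mapq,
                    reads$len,
                    vapply(reads$len, function(l)
                      paste(rep("A", l), collapse = ""), character(1)))
  }
  sam <- file.path(dir, "fixture.sam")
  writeLines(c(hd, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# tile a target with uniform perfect-match reads giving exact coverage `cov`
uniformReads <- function(rname, targetLen, readLen = 100L, cov = 10L) {
  starts <- seq(1L, targetLen, by = readLen)
  starts <- starts[starts + readLen - 1L <= targetLen]
  data.frame(
    qname = sprintf("%s_r%05d", rname,
                    seq_len(length(starts) * cov)),
    rname = rname,
    pos = rep(starts, each = cov),
    mapq = 60L,
    len = readLen)
}

# noiseless DepthBins built directly from per-chromosome depth vectors
flatBins <- function(depths, binSize = 10000L) {
  df <- do.call(rbind, lapply(seq_along(depths), function(i) {
    n <- length(depths[[i]])
    data.frame(sequence = names(depths)[i],
               start = (seq_len(n) - 1L) * binSize,
               end = seq_len(n) * binSize,
               depth = depths[[i]])
  }))
  depthBins(df, binSize = binSize, source = "table")
}
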