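randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("planted terminal arrays are found with exact copy counts", {
  set.seed(11)
  mid <- randomSeq(20000, 11)
  s <- Biostrings::DNAStringSet(paste0(strrep("CCCCTAA", 8), mid,
                                       strrep("TTAGGGG", 8)))
  names(s) <- "ctg"
  hits <- scanTelomeres(s)
  expect_identical(nrow(hits), 2L)
  expect_setequal(hits$side, c("left", "right"))
  expect_true(all(hits$copies == 8L))
  expect_identical(hits$start[hits$side == "left"], 0L)
  expect_identical(hits$end[hits$side == "right"], 20112L)
})

test_that("sequences without telomere motifs give an empty hit table", {
  s <- Biostrings::DNAStringSet(c(ctg = randomSeq(20000, 13)))
  expect_identical(nrow(scanTelomeres(s)), 0L)
})

test_that("mismatches inside an array are tolerated up to the configured fraction", {
  arr <- strrep("CCCCTAA", 20)
  substr(arr, 70, 70) <- "G"           # one substitution mid-array
  s <- Biostrings::DNAStringSet(c(ctg = paste0(arr, randomSeq(5000, 17))))
  hits <- scanTelomeres(s)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$copies, 20L)
  expect_identical(hits$start, 0L)
  expect_identical(hits$end, 140L)
  # with zero tolerance the array splits and the 5' fragment is short
  strict <- scanTelomeres(s, maxMismatchFraction = 0)
  expect_true(all(strict$copies < 20L))
})

test_that("reverse-complementing a contig mirrors telomere sides", {
  s <- Biostrings::DNAStringSet(c(ctg = paste0(strrep("CCCCTAA", 9),
                                               randomSeq(15000, 19))))
  fwd <- scanTelomeres(s)
  expect_identical(fwd$side, "left")
  rc <- Biostrings::reverseComplement(s)
  names(rc) <- "ctg"
  rev <- scanTelomeres(rc)
  expect_identical(rev$side, "right")
  expect_identical(rev$copies, fwd$copies)
  expect_identical(rev$start, 15000L + 63L - fwd$end)
})

test_that("scanner output equals the generator truth table on a seeded fixture", {
  asm <- generateAssembly(l7AssemblyPlan(), seed = 7)
  hits <- scanTelomeres(asm$sequences)
  truth <- asm$features[asm$features$feature == "telomere", ]
  key <- function(d) d[order(d$contig, d$start),
                       c("contig", "side", "start", "end", "copies", "unit")]
  got <- key(hits)
  want <- key(truth)
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("raising minCopies never increases the number of hits", {
  asm <- generateAssembly(l7AssemblyPlan(telomereCopies = 15), seed = 21)
  counts <- vapply(c(1, 5, 10, 15, 16, 30), function(mc)
    nrow(scanTelomeres(asm$sequences, minCopies = mc)), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[6], 0L)
})

test_that("rDNA search finds exact and diverged planted arrays", {
  gt <- genomeTruth(c(ctg = 30000),
                    rdnaPlan = data.frame(contig = "ctg", offset = 10000,
                                          copies = 2L))
  asm <- generateAssembly(gt, seed = 23)
  loci <- detectRdna(asm$sequences)
  expect_identical(nrow(loci), 1L)
  expect_equal(loci$identity, 100)
  expect_identical(loci$start, 10000L)
  expect_identical(loci$end, 15000L)
  expect_false(loci$terminal)

  # 5% substitutions: still detected at minIdentity 90, with identity close
  # to an independent global-alignment oracle on the planted pair
  unit <- rdnaUnit()
  set.seed(29)
  chars <- strsplit(as.character(unit), "")[[1]]
  mutPos <- sample(length(chars), round(0.05 * length(chars)))
  for (p in mutPos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  mutated <- Biostrings::DNAString(paste(chars, collapse = ""))
  s <- Biostrings::DNAStringSet(c(ctg = paste0(
    randomSeq(4000, 29), as.character(mutated), randomSeq(4000, 31))))
  loci <- detectRdna(s, minIdentity = 90)
  expect_identical(nrow(loci), 1L)
  oracle <- Biostrings::pid(Biostrings::pairwiseAlignment(unit, mutated))
  expect_lt(abs(loci$identity - oracle), 2)
})

test_that("rDNA search rejects empty references and reports nothing when absent", {
  s <- Biostrings::DNAStringSet(c(ctg = randomSeq(20000, 37)))
  expect_identical(nrow(detectRdna(s)), 0L)
  expect_error(detectRdna(s, references = Biostrings::DNAStringSet("")),
               "empty reference")
})

test_that("contig accounting reproduces the strain contig classes", {
  # reference-like: 14 double-sided + 1 single-telomere-plus-terminal-rDNA
  asm <- generateAssembly(l7AssemblyPlan(), seed = 42)
  sc <- scanAssembly(asm$sequences)
  expect_identical(sc$accounting$n_double_sided, 14L)
  expect_identical(sc$accounting$n_single_plus_rdna, 1L)
  expect_identical(sc$accounting$chromosome_count_strict, 14L)
  expect_identical(sc$accounting$chromosome_count_extended, 15L)

  # Pr2C-like: 13 double + 1 single-with-rDNA + 2 single-only
  asm2 <- generateAssembly(pr2cAssemblyPlan(), seed = 43)
  sc2 <- scanAssembly(asm2$sequences)
  expect_identical(sc2$accounting$n_double_sided, 13L)
  expect_identical(sc2$accounting$n_single_plus_rdna, 1L)
  expect_identical(sc2$accounting$n_single_only, 2L)
  expect_identical(sc2$accounting$chromosome_count_strict, 13L)
  expect_identical(sc2$accounting$chromosome_count_extended, 14L)
})

test_that("assemblies without telomeres count zero chromosomes", {
  s <- Biostrings::DNAStringSet(c(a = randomSeq(5000, 41),
                                  b = randomSeq(5000, 43)))
  sc <- scanAssembly(s)
  expect_identical(sc$accounting$chromosome_count_strict, 0L)
  expect_identical(sc$accounting$chromosome_count_extended, 0L)
  expect_identical(sc$accounting$n_none, 2L)
})

test_that("contigs with more than two terminal arrays are flagged, not fixed", {
  asm <- generateAssembly(prtAssemblyPlan(), seed = 47)
  sc <- scanAssembly(asm$sequences)
  ann <- sc$annotations
  expect_true(ann$multiTelomereFlag[ann$contig == "contig1"])
  expect_identical(ann$nTerminalArrays[ann$contig == "contig1"], 3L)
  expect_identical(sc$accounting$n_double_sided, 11L)
  expect_identical(sc$accounting$n_single_only, 5L)
  expect_identical(sc$accounting$n_none, 1L)
})

test_that("duplicate contig ids are rejected by accounting", {
  ann <- data.frame(contig = c("a", "a"), length = 10,
                    telomereClass = "none", nTerminalArrays = 0L,
                    multiTelomereFlag = FALSE, nRdna = 0L,
                    terminalRdnaSides = "", completeness = "partial")
  expect_error(accountChromosomes(ann), "duplicate contig ids")
})

test_that("reverse-complementing a whole assembly preserves accounting", {
  asm <- generateAssembly(pr2cAssemblyPlan(), seed = 51)
  fwd <- scanAssembly(asm$sequences)
  rc <- Biostrings::reverseComplement(asm$sequences)
  names(rc) <- names(asm$sequences)
  rev <- scanAssembly(rc)
  expect_identical(fwd$accounting, rev$accounting)
  expect_identical(sum(fwd$telomeres$side == "left"),
                   sum(rev$telomeres$side == "right"))
  expect_identical(sum(fwd$telomeres$side == "right"),
                   sum(rev$telomeres$side == "left"))
})
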