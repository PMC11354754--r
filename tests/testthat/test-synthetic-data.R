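test_that("generateAssembly plants telomere arrays flush with contig ends", {
  gt <- genomeTruth(c(ctg = 50000),
                    telomerePlan = data.frame(contig = "ctg",
                                              side = c("left", "right"),
                                              copies = 10L))
  asm <- generateAssembly(gt, seed = 1)
  s <- as.character(asm$sequences[[1]])
  expect_identical(substr(s, 1, 70), strrep("CCCCTAA", 10))
  expect_identical(substr(s, 49931, 50000), strrep("TTAGGGG", 10))
  expect_identical(nchar(s), 50000L)
})

test_that("the fifteen-contig reference plan yields 29 telomere and 1 rDNA truth entries", {
  asm <- generateAssembly(l7AssemblyPlan(), seed = 42)
  expect_length(asm$sequences, 15L)
  expect_identical(sum(asm$features$feature == "telomere"), 29L)
  expect_identical(sum(asm$features$feature == "rdna"), 1L)
})

test_that("assembly generation is deterministic in plan and seed", {
  a <- generateAssembly(l7AssemblyPlan(), seed = 9)
  b <- generateAssembly(l7AssemblyPlan(), seed = 9)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$features, b$features)
  c <- generateAssembly(l7AssemblyPlan(), seed = 10)
  expect_false(identical(as.character(a$sequences),
                         as.character(c$sequences)))
})

test_that("plans exceeding the contig are rejected with a diagnostic", {
  expect_error(
    genomeTruth(c(ctg = 100),
                telomerePlan = data.frame(contig = "ctg", side = "left",
                                          copies = 20L)),
    "exceeds contig length")
  expect_error(
    genomeTruth(c(ctg = 1000),
                rdnaPlan = data.frame(contig = "ctg", offset = 0,
                                      unitLength = 600, copies = 2L)),
    "beyond contig")
})

test_that("noiseless depth simulation returns the model mean exactly", {
  strain <- strainConfig("hk", copyVec(chr15 = 2), baseDepth = 50,
                         dispersion = 0, outlierFraction = 0)
  sim <- simulateDepth(referenceChromosomeLengths(), strain)
  df <- as.data.frame(sim$bins)
  expect_true(all(df$depth[df$sequence == "chr15"] == 100))
  expect_true(all(df$depth[df$sequence != "chr15"] == 50))
  expect_identical(sim$truth$trueFold[sim$truth$seqnames == "chr15"], 2)
})

test_that("a dikaryon nucleus mixture gives fractional true folds", {
  strain <- strainConfig("dk", rbind(copyVec(), copyVec(chr14 = 2)))
  sim <- simulateDepth(referenceChromosomeLengths(), strain)
  expect_equal(sim$truth$trueFold[sim$truth$seqnames == "chr14"], 1.5)
  expect_true(all(sim$truth$trueFold[sim$truth$seqnames != "chr14"] == 1))
})

test_that("simulated bin means converge to the model mean", {
  lens <- c(big = 1e7)
  strain <- strainConfig("one", stats::setNames(1L, "big"), baseDepth = 50,
                         dispersion = 0.1, outlierFraction = 0, seed = 3L)
  sim <- simulateDepth(lens, strain, binSize = 1000)   # 10,000 bins
  expect_gte(length(binDepth(sim$bins)), 10000L)
  expect_lt(abs(mean(binDepth(sim$bins)) - 50) / 50, 0.01)
})

test_that("depth simulation rejects invalid genomes and is seed-reproducible", {
  strain <- strainConfig("s", copyVec(n = 2L))
  expect_error(simulateDepth(c(chr1 = 0, chr2 = 100), strain), "zero-length")
  lens <- smallLengths(2L)
  a <- simulateDepth(lens, strain)
  b <- simulateDepth(lens, strain)
  expect_identical(binDepth(a$bins), binDepth(b$bins))
})

test_that("read sampling follows length-times-copies rates", {
  lens <- smallLengths(4L)
  lens[2] <- 4e6
  euploid <- strainConfig("eu", copyVec(n = 4L), seed = 5L)
  rs <- simulateReads(lens, euploid, nReads = 10000)
  p <- as.numeric(lens) / sum(as.numeric(lens))
  counts <- table(factor(rs$origins$seqnames, levels = names(lens)))
  expect_true(all(abs(counts - 10000 * p) <=
                  3 * sqrt(10000 * p * (1 - p))))

  dup <- strainConfig("dup", copyVec(chr4 = 2, n = 4L), seed = 5L)
  n <- 100000
  share <- function(strain) {
    o <- simulateReads(lens, strain, nReads = n)$origins
    mean(o$seqnames == "chr4")
  }
  ratio <- share(dup) / share(euploid)
  expected <- (2 * lens[[4]] / (sum(as.numeric(lens)) + lens[[4]])) /
    (lens[[4]] / sum(as.numeric(lens)))
  expect_lt(abs(ratio - expected) / expected, 0.05)
})

test_that("zero requested reads is a valid empty result", {
  rs <- simulateReads(smallLengths(2L), strainConfig("s", copyVec(n = 2L)),
                      nReads = 0)
  expect_identical(nrow(rs$origins), 0L)
  expect_null(rs$reads)
})

test_that("read sequences match their origin coordinates", {
  gt <- genomeTruth(c(ctg = 20000))
  asm <- generateAssembly(gt, seed = 2)
  strain <- strainConfig("s", stats::setNames(1L, "ctg"), seed = 2L)
  rs <- simulateReads(c(ctg = 20000), strain, nReads = 20, readLength = 80,
                      sequences = asm$sequences)
  i <- which(rs$origins$strand == "+")[1]
  expect_identical(
    as.character(rs$reads[[i]]),
    as.character(Biostrings::subseq(asm$sequences[["ctg"]],
                                    rs$origins$start[i] + 1, width = 80)))
  j <- which(rs$origins$strand == "-")[1]
  expect_identical(
    as.character(rs$reads[[j]]),
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(asm$sequences[["ctg"]],
                         rs$origins$start[j] + 1, width = 80))))
})

test_that("cohort truth labels match the planted copy configurations", {
  l12 <- exampleCohort("L12", seed = 4)
  expect_identical(unname(table(cohortLabels(l12)$verdict)["aneuploid"]), 3L)
  expect_identical(unname(table(cohortLabels(l12)$verdict)["euploid"]), 5L)

  l14 <- exampleCohort("L14", seed = 4)
  lab <- cohortLabels(l14)
  expect_identical(nrow(lab), 20L)
  expect_identical(sum(lab$verdict == "aneuploid"), 15L)
  expect_identical(sum(grepl("chr15:2", lab$duplicated)), 10L)
  expect_identical(sum(grepl("chr15:3", lab$duplicated)), 4L)
  expect_identical(sum(grepl("chr15:4", lab$duplicated)), 1L)
  # the S10/S13/S15 configurations carry a second, 1.5x chromosome
  expect_identical(sum(grepl("chr14:1.5", lab$duplicated)), 1L)
  expect_identical(sum(grepl("chr13:1.5", lab$duplicated)), 1L)
  expect_identical(sum(grepl("chr11:1.5", lab$duplicated)), 1L)
})

test_that("an all-euploid cohort has zero aneuploid labels; empty cohorts fail", {
  parent <- exampleStrain("L12")
  off <- stats::setNames(replicate(3, copyVec(), simplify = FALSE),
                         paste0("o", 1:3))
  coh <- buildCohort(parent, off, truth = smallLengths(15L, 5e5), seed = 1)
  expect_true(all(cohortLabels(coh)$verdict == "euploid"))
  expect_error(buildCohort(parent, list(), seed = 1), ">= 1 offspring")
})
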