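summaryOf <- function(depths) {
  data.frame(seqnames = paste0("chr", seq_along(depths)), nBins = 100L,
             robustDepth = depths, madDepth = 1, maskedFraction = 0)
}

test_that("raw folds are robust-depth over the median baseline", {
  est <- estimateFolds(summaryOf(c(50, 50, 50, 100)))
  expect_equal(est$baseline, 50)
  expect_equal(est$folds$rawFold, c(1, 1, 1, 2))

  est <- estimateFolds(summaryOf(rep(62, 6)))
  expect_true(all(est$folds$rawFold == 1))

  a <- estimateFolds(summaryOf(c(50, 50, 50, 100)))
  b <- estimateFolds(summaryOf(c(50, 50, 50, 100) * 3))
  expect_equal(a$folds$rawFold, b$folds$rawFold)

  expect_error(estimateFolds(summaryOf(50)), ">= 2 chromosomes")
  expect_error(estimateFolds(summaryOf(c(0, 0, 0))), "baseline depth is zero")
})

test_that("grid assignment follows the relative tolerance rule", {
  eu <- classifyFolds(summaryOf(c(50, 50, 50, 51)), bootstrapReps = 0)
  expect_identical(verdict(eu), "euploid")
  expect_true(all(foldTable(eu)$multiple == 1))

  an <- classifyFolds(summaryOf(c(rep(50, 14), 101.5)), bootstrapReps = 0)
  expect_identical(verdict(an), "aneuploid")
  expect_equal(duplicatedChromosomes(an)$multiple, 2)
  expect_identical(duplicatedChromosomes(an)$seqnames, "chr15")

  amb <- classifyFolds(summaryOf(c(50, 50, 50, 62.5)),
                       grid = c(1, 1.5, 2), tolerance = 0.1,
                       bootstrapReps = 0)
  expect_identical(verdict(amb), "ambiguous")
  expect_true(is.na(foldTable(amb)$multiple[4]))

  expect_error(classifyFolds(summaryOf(c(50, 50)), grid = numeric(),
                             bootstrapReps = 0), "empty")
  expect_error(classifyFolds(summaryOf(c(50, 50)), grid = c(1.5, 2),
                             bootstrapReps = 0), "contain 1")
})

test_that("noiseless nucleus-weighted copies give exact fractional folds", {
  strain <- strainConfig("dk", rbind(copyVec(chr14 = 1), copyVec(chr14 = 2)),
                         dispersion = 0, outlierFraction = 0)
  sim <- simulateDepth(referenceChromosomeLengths(), strain)
  call <- classifyFolds(sim$bins, bootstrapReps = 0)
  ft <- foldTable(call)
  expect_equal(ft$rawFold[ft$seqnames == "chr14"], 1.5)
  expect_equal(ft$multiple[ft$seqnames == "chr14"], 1.5)
})

test_that("folds and verdicts recover the study strain configurations", {
  lens <- referenceChromosomeLengths()
  dupsOf <- function(name, seed) {
    sim <- simulateDepth(lens, exampleStrain(name, seed = seed))
    duplicatedChromosomes(classifyFolds(sim$bins, strainId = name,
                                        bootstrapReps = 0))
  }
  d <- dupsOf("S10", 3)
  expect_identical(d$seqnames, c("chr14", "chr15"))
  expect_equal(d$multiple, c(1.5, 2))

  d <- dupsOf("L14", 5)
  expect_identical(d$seqnames, "chr15")
  expect_equal(d$multiple, 3)
})

test_that("calls are invariant under global depth scaling", {
  sim <- simulateDepth(referenceChromosomeLengths(),
                       exampleStrain("Pr2C", seed = 23))
  call <- classifyFolds(sim$bins, bootstrapReps = 50, seed = 23)
  gr <- binGRanges(sim$bins)
  gr$depth <- gr$depth * 2.7
  scaled <- classifyFolds(depthBins(gr, binSize = 10000),
                          bootstrapReps = 50, seed = 23)
  expect_equal(foldTable(scaled)$rawFold, foldTable(call)$rawFold)
  expect_identical(foldTable(scaled)$multiple, foldTable(call)$multiple)
  expect_equal(foldTable(scaled)$confidence, foldTable(call)$confidence)
  expect_identical(verdict(scaled), verdict(call))
})

test_that("assignment confidence does not rise with noisier coverage", {
  lens <- referenceChromosomeLengths()
  confOf <- function(dispersion) {
    strain <- strainConfig("s", rbind(copyVec(), copyVec(chr15 = 2)),
                           dispersion = dispersion, seed = 31L)
    call <- classifyFolds(simulateDepth(lens, strain)$bins,
                          bootstrapReps = 100, seed = 31)
    ft <- foldTable(call)
    ft$confidence[ft$seqnames == "chr15"]
  }
  expect_gte(confOf(0.02), confOf(0.8))
})

test_that("nuclear composition enumeration matches the strain models", {
  hk <- inferNuclearComposition(copyVec(chr15 = 2) * 1.0, nucleusCount = 1)
  expect_length(hk, 1L)
  expect_identical(unname(hk[[1]]@genotypes[1, "chr15"]), 2L)

  dk <- inferNuclearComposition(
    stats::setNames(c(rep(1, 14), 1.5), paste0("chr", 1:15)),
    nucleusCount = 2)
  expect_length(dk, 1L)
  expect_identical(unname(dk[[1]]@genotypes[, "chr15"]), c(1L, 2L))
  expect_equal(dk[[1]]@weights, c(0.5, 0.5))

  tri <- inferNuclearComposition(
    stats::setNames(c(rep(1, 14), 3), paste0("chr", 1:15)), nucleusCount = 2)
  splits <- lapply(tri, function(m)
    sort(unname(rep(m@genotypes[, "chr15"], round(m@weights * 2)))))
  expect_identical(splits, list(c(3L, 3L), c(2L, 4L), c(1L, 5L)))
})

test_that("non-integer targets need a mixture or are flagged infeasible", {
  m <- stats::setNames(c(rep(1, 14), 1.5), paste0("chr", 1:15))
  bad <- inferNuclearComposition(m, nucleusCount = 1)
  expect_false(bad[[1]]@feasible)

  mix <- inferNuclearComposition(m, nucleusCount = 1, allowMixture = TRUE)
  expect_true(mix[[1]]@feasible)
  expect_identical(unname(mix[[1]]@genotypes[, "chr15"]), c(1L, 2L))
  expect_equal(mix[[1]]@weights, c(0.5, 0.5))

  low <- inferNuclearComposition(
    stats::setNames(c(1, 0.5), c("chr1", "chr2")), nucleusCount = 1,
    allowMixture = TRUE)
  expect_false(low[[1]]@feasible)
})

test_that("composition enumeration equals brute force for small nucleus counts", {
  bruteSplits <- function(total, parts) {
    g <- expand.grid(rep(list(seq_len(total)), parts))
    g <- g[rowSums(g) == total, , drop = FALSE]
    unique(t(apply(g, 1, sort)))
  }
  for (nuclei in 2:4) {
    for (multiple in c(1.5, 2, 3, 4)) {
      total <- multiple * nuclei
      if (abs(total - round(total)) > 1e-9) next
      m <- stats::setNames(c(1, 1, 1, multiple), paste0("chr", 1:4))
      res <- inferNuclearComposition(m, nucleusCount = nuclei)
      got <- t(vapply(res, function(x)
        sort(rep(x@genotypes[, "chr4"], round(x@weights * nuclei))),
        integer(nuclei)))
      want <- bruteSplits(as.integer(total), nuclei)
      keyG <- sort(unname(apply(got, 1, paste, collapse = ",")))
      keyW <- sort(unname(apply(want, 1, paste, collapse = ",")))
      expect_identical(keyG, keyW)
    }
  }
})

test_that("cohort screening tallies verdicts and duplications exactly", {
  lens <- referenceChromosomeLengths()
  strains <- c("L2", "L4", "L11", "L12", "L14", "L43")
  calls <- lapply(strains, function(nm) {
    sim <- simulateDepth(lens, exampleStrain(nm, seed = 7))
    classifyFolds(sim$bins, strainId = nm, bootstrapReps = 0)
  })
  sc <- screenCohort(calls)
  expect_identical(unname(sc$verdicts["aneuploid"]), 3L)
  expect_identical(unname(sc$verdicts["euploid"]), 3L)
  expect_identical(as.character(sc$byChromosome$seqnames), "chr15")
  expect_identical(sc$byChromosome$n, 3L)

  expect_error(screenCohort(calls[c(1, 1)]), "duplicate strain ids")
  expect_error(screenCohort(list()), ">= 1")

  euCalls <- lapply(c("L4", "L11"), function(nm) {
    sim <- simulateDepth(lens, exampleStrain(nm, seed = 9))
    classifyFolds(sim$bins, strainId = nm, bootstrapReps = 0)
  })
  sc <- screenCohort(euCalls)
  expect_identical(unname(sc$verdicts["aneuploid"]), 0L)
  expect_identical(nrow(sc$byChromosome), 0L)
})
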