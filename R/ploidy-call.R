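#' @include AllClasses.R AllGenerics.R depth-profile.R
NULL

#' Default fold grid
#'
#' The discrete depth-fold multiples onto which raw folds are classified:
#' the multiples observed across strains (1.5, 2, 3, 4) plus 1 (euploid) and
#' the midpoints 2.5 and 3.5 so that intermediate folds are representable
#' rather than forced onto a neighbour.
#'
#' @return numeric vector `c(1, 1.5, 2, 2.5, 3, 3.5, 4)`.
#' @export
defaultFoldGrid <- function() c(1, 1.5, 2, 2.5, 3, 3.5, 4)

#' Estimate per-chromosome depth folds
#'
#' The baseline is the median of the per-chromosome robust depths (default)
#' or the mode of their kernel density (`baselineMethod = "mode"`); the raw
#' fold of a chromosome is its robust depth divided by the baseline. The
#' median baseline is robust because duplicated chromosomes are a minority
#' of the karyotype.
#'
#' @param chromDepth per-chromosome summary from
#'   [summarizeChromosomeDepth()] (>= 2 chromosomes).
#' @param baselineMethod "median" or "mode".
#' @return list with `folds` (the input data.frame plus a `rawFold` column)
#'   and `baseline` (x coverage).
#' @export
#' @examples
#' cd <- data.frame(seqnames = paste0("chr", 1:4), nBins = 100,
#'                  robustDepth = c(50, 50, 50, 100))
#' estimateFolds(cd)$folds$rawFold
estimateFolds <- function(chromDepth, baselineMethod = c("median", "mode")) {
  baselineMethod <- match.arg(baselineMethod)
  if (nrow(chromDepth) < 2L)
    stop("fold estimation needs >= 2 chromosomes")
  d <- chromDepth$robustDepth
  baseline <- if (baselineMethod == "median") stats::median(d) else {
    dens <- stats::density(d)
    dens$x[which.max(dens$y)]
  }
  if (baseline <= 0) stop("baseline depth is zero")
  chromDepth$rawFold <- d / baseline
  list(folds = chromDepth, baseline = baseline)
}

# nearest-grid assignment with relative tolerance; NA when outside tolerance
.assignGrid <- function(raw, grid, tolerance) {
  vapply(raw, function(f) {
    g <- grid[which.min(abs(f - grid))]
    if (abs(f - g) / g <= tolerance) g else NA_real_
  }, numeric(1))
}

.verdictOf <- function(multiple) {
  if (any(is.na(multiple))) "ambiguous"
  else if (any(multiple > 1)) "aneuploid"
  else "euploid"
}

#' Classify depth folds onto a discrete copy-number grid
#'
#' Computes per-chromosome robust depths and raw folds, assigns each fold to
#' the nearest grid value when the relative deviation is within `tolerance`
#' (otherwise the chromosome is left unassigned), and derives the strain
#' verdict: `ambiguous` when any chromosome is unassigned (ambiguity is
#' explicit, never silently rounded), otherwise `aneuploid` when any
#' assigned multiple exceeds 1, otherwise `euploid`. Confidence of each
#' assignment is the fraction of bin-level bootstrap resamples (whole
#' pipeline: robust depth, baseline, fold, assignment) agreeing with the
#' point assignment.
#'
#' @param x a [DepthBins-class], or a per-chromosome summary data.frame from
#'   [summarizeChromosomeDepth()] (in which case `bootstrapReps` must be 0
#'   and confidences are NA).
#' @param strainId strain identifier recorded in the call.
#' @param grid sorted ascending fold grid containing 1.
#' @param tolerance relative assignment tolerance.
#' @param baselineMethod passed to [estimateFolds()].
#' @param trimFraction,madK passed to [summarizeChromosomeDepth()].
#' @param bootstrapReps number of bin resamples for confidence (0 to skip).
#' @param seed seed for the bootstrap.
#' @return a [KaryotypeCall-class].
#' @export
#' @examples
#' sim <- simulateDepth(referenceChromosomeLengths(), exampleStrain("L7"))
#' call <- classifyFolds(sim$bins, strainId = "L7", bootstrapReps = 50)
#' verdict(call)
#' duplicatedChromosomes(call)
classifyFolds <- function(x, strainId = "strain", grid = defaultFoldGrid(),
                          tolerance = 0.12,
                          baselineMethod = c("median", "mode"),
                          trimFraction = 0.1, madK = 5,
                          bootstrapReps = 200, seed = 1L) {
  baselineMethod <- match.arg(baselineMethod)
  if (!length(grid)) stop("fold grid must not be empty")
  if (is.unsorted(grid, strictly = TRUE))
    stop("fold grid must be sorted ascending")
  if (!any(grid == 1)) stop("fold grid must contain 1")
  fromBins <- is(x, "DepthBins")
  if (!fromBins && bootstrapReps > 0)
    stop("bootstrap confidence needs the DepthBins; ",
         "set bootstrapReps = 0 for a summary-only call")
  cs <- if (fromBins)
    summarizeChromosomeDepth(x, trimFraction = trimFraction, madK = madK)
  else as.data.frame(x)
  est <- estimateFolds(cs, baselineMethod)
  folds <- est$folds
  folds$multiple <- .assignGrid(folds$rawFold, grid, tolerance)
  folds$confidence <- NA_real_
  if (fromBins && bootstrapReps > 0) {
    df <- as.data.frame(x)
    df <- df[df$end - df$start == x@binSize, ]
    perChrom <- split(df$depth, df$sequence)[folds$seqnames]
    set.seed(deriveSeed(seed, paste0("bootstrap/", strainId)))
    agree <- matrix(0L, nrow(folds), bootstrapReps)
    robustOne <- function(d) {
      med <- stats::median(d); madv <- stats::mad(d)
      keep <- abs(d - med) <= madK * madv
      if (!any(keep)) keep <- rep(TRUE, length(d))
      mean(d[keep], trim = trimFraction)
    }
    for (r in seq_len(bootstrapReps)) {
      rd <- vapply(perChrom, function(d)
        robustOne(d[sample.int(length(d), replace = TRUE)]), numeric(1))
      base <- if (baselineMethod == "median") stats::median(rd) else {
        dens <- stats::density(rd); dens$x[which.max(dens$y)]
      }
      mult <- .assignGrid(rd / base, grid, tolerance)
      same <- (is.na(mult) & is.na(folds$multiple)) |
              (!is.na(mult) & !is.na(folds$multiple) &
               mult == folds$multiple)
      agree[, r] <- as.integer(same)
    }
    folds$confidence <- rowMeans(agree)
  }
  dup <- folds[!is.na(folds$multiple) & folds$multiple > 1,
               c("seqnames", "multiple"), drop = FALSE]
  rownames(dup) <- NULL
  new("KaryotypeCall", strainId = strainId, folds = folds,
      baseline = est$baseline, grid = as.numeric(grid),
      tolerance = as.numeric(tolerance), verdict = .verdictOf(folds$multiple),
      duplicated = dup)
}

# ordered compositions of `total` into `parts` summands, each >= 1
.compositions <- function(total, parts) {
  if (parts == 1L) return(matrix(total, 1L, 1L))
  out <- list()
  for (first in seq_len(total - parts + 1L)) {
    rest <- .compositions(total - first, parts - 1L)
    out[[first]] <- cbind(first, rest)
  }
  unname(do.call(rbind, out))
}

.mixtureFromGenotypes <- function(genotypes, weights, nucleusCount, note = "") {
  o <- do.call(order, as.data.frame(genotypes))
  genotypes <- genotypes[o, , drop = FALSE]
  weights <- weights[o]
  key <- apply(genotypes, 1L, paste, collapse = ",")
  agg <- tapply(weights, key, sum)
  uniq <- genotypes[!duplicated(key), , drop = FALSE]
  new("NucleusMixture", genotypes = uniq,
      weights = as.numeric(agg[apply(uniq, 1L, paste, collapse = ",")]),
      nucleusCount = as.integer(nucleusCount), feasible = TRUE, note = note)
}

#' Enumerate nuclear compositions compatible with a karyotype call
#'
#' Given assigned per-chromosome multiples, enumerates the ways the
#' implied total copy number of each chromosome (`multiple x nucleusCount`,
#' with a baseline of one copy per nucleus) can be split across the
#' strain's nuclei with at least one copy each. For integer totals all
#' unordered splits are enumerated (e.g. a dikaryon at multiple 1.5 has
#' total 3 and the single split 1+2: one euploid and one duplicated
#' nucleus). A non-integer total is unreachable by a fixed set of nuclei;
#' with `allowMixture = TRUE` it is represented as a weighted mixture of two
#' cell sub-populations whose totals bracket the target (e.g. a homokaryon
#' at multiple 1.5 becomes an equal mixture of 1-copy and 2-copy nuclei,
#' the representation used for protoplast strains that may carry more than
#' one nucleus of the same mating type); without it an infeasibility result
#' is returned. Results are ordered by parsimony: fewest distinct nucleus
#' genotypes, then smallest maximum copy number.
#'
#' @param x a [KaryotypeCall-class] with all folds assigned, or a named
#'   vector of per-chromosome multiples.
#' @param nucleusCount nuclei per cell (1 = homokaryon, 2 = dikaryon).
#' @param allowMixture represent non-integer totals as two-component cell
#'   mixtures instead of failing.
#' @param maxResults cap on the number of returned compositions.
#' @return list of [NucleusMixture-class], parsimony-ordered. Infeasible
#'   targets yield a single element with `feasible = FALSE`.
#' @export
#' @examples
#' m <- stats::setNames(c(rep(1, 14), 1.5), paste0("chr", 1:15))
#' inferNuclearComposition(m, nucleusCount = 2)[[1]]
inferNuclearComposition <- function(x, nucleusCount = 1L,
                                    allowMixture = FALSE,
                                    maxResults = 100L) {
  multiples <- if (is(x, "KaryotypeCall")) {
    stats::setNames(x@folds$multiple, x@folds$seqnames)
  } else x
  if (any(is.na(multiples)))
    stop("all folds must be assigned before composition inference")
  nucleusCount <- as.integer(nucleusCount)
  chroms <- names(multiples)
  target <- multiples * nucleusCount
  infeasible <- function(note)
    list(new("NucleusMixture", genotypes = matrix(integer(), 0, 0),
             weights = numeric(), nucleusCount = nucleusCount,
             feasible = FALSE, note = note))
  if (any(target < nucleusCount - 1e-9))
    return(infeasible(
      "fold below 1 is unreachable with >= 1 copy per nucleus"))
  isInt <- abs(target - round(target)) < 1e-9
  if (all(isInt)) {
    target <- as.integer(round(target))
    perChromSplits <- lapply(target, .compositions, parts = nucleusCount)
    varying <- which(vapply(perChromSplits, nrow, integer(1)) > 1L)
    base <- matrix(1L, nucleusCount, length(chroms),
                   dimnames = list(NULL, chroms))
    for (c in seq_along(chroms))
      base[, c] <- perChromSplits[[c]][1L, ]
    combos <- list(base)
    for (c in varying) {
      sp <- perChromSplits[[c]]
      combos <- unlist(lapply(combos, function(g) {
        lapply(seq_len(nrow(sp)), function(k) {
          g[, c] <- sp[k, ]; g
        })
      }), recursive = FALSE)
      if (length(combos) > 50000L)
        stop("composition space too large; reduce duplicated chromosomes ",
             "or nucleusCount")
    }
    mixtures <- lapply(combos, function(g)
      .mixtureFromGenotypes(g, rep(1 / nucleusCount, nucleusCount),
                            nucleusCount))
    # drop duplicates (splits equal up to nucleus relabeling)
    sig <- vapply(mixtures, function(m)
      paste(apply(m@genotypes, 1L, paste, collapse = ","), m@weights,
            collapse = "|"), character(1))
    mixtures <- mixtures[!duplicated(sig)]
  } else {
    if (!allowMixture)
      return(infeasible(paste0(
        "non-integer total copies (",
        paste(sprintf("%s=%g", chroms[!isInt], target[!isInt]),
              collapse = ", "),
        ") with a fixed nucleus set; set allowMixture = TRUE")))
    # two-component population mixture per non-integer chromosome,
    # components combined assuming independence across chromosomes
    comps <- list(list(tot = ifelse(isInt, round(target), floor(target)),
                       w = 1))
    for (c in which(!isInt)) {
      f <- target[c] - floor(target[c])
      comps <- unlist(lapply(comps, function(cp) {
        lo <- cp; lo$w <- cp$w * (1 - f)
        hi <- cp; hi$tot[c] <- floor(target[c]) + 1; hi$w <- cp$w * f
        list(lo, hi)
      }), recursive = FALSE)
    }
    genotypes <- NULL; weights <- numeric()
    for (cp in comps) {
      if (cp$w <= 0) next
      g <- matrix(1L, nucleusCount, length(chroms),
                  dimnames = list(NULL, chroms))
      for (c in seq_along(chroms)) {
        sp <- .compositions(as.integer(cp$tot[c]), nucleusCount)
        # most parsimonious split: the most even one
        ev <- which.min(apply(sp, 1L, max))
        g[, c] <- sp[ev, ]
      }
      genotypes <- rbind(genotypes, g)
      weights <- c(weights, rep(cp$w / nucleusCount, nucleusCount))
    }
    mixtures <- list(.mixtureFromGenotypes(
      genotypes, weights, nucleusCount,
      note = "two-component cell mixture for non-integer copy targets"))
  }
  ord <- order(vapply(mixtures, function(m) nrow(m@genotypes), integer(1)),
               vapply(mixtures, function(m) max(m@genotypes), integer(1)))
  mixtures <- mixtures[ord]
  if (length(mixtures) > maxResults) mixtures <- mixtures[seq_len(maxResults)]
  mixtures
}

#' Tally karyotype calls across a cohort
#'
#' @param calls list of [KaryotypeCall-class] with unique strain ids.
#' @return list with `n`, `verdicts` (named counts over euploid / aneuploid /
#'   ambiguous), `byChromosome` (duplications per chromosome),
#'   `byMultiple` (duplications per chromosome and multiple), and `strains`
#'   (one row per strain: `strainId`, `verdict`, `duplicated`).
#' @export
#' @examples
#' coh <- exampleCohort("L12", seed = 2)
#' calls <- lapply(seq_along(coh@configs), function(i)
#'   classifyFolds(coh@depth[[i]], strainId = coh@labels$strainId[i],
#'                 bootstrapReps = 0))
#' screenCohort(calls)$verdicts
screenCohort <- function(calls) {
  if (!length(calls)) stop("need >= 1 karyotype call")
  ids <- vapply(calls, strainId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate strain ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  verd <- vapply(calls, verdict, character(1))
  verdicts <- table(factor(verd, levels = c("euploid", "aneuploid",
                                            "ambiguous")))
  dups <- do.call(rbind, lapply(calls, function(cl) {
    d <- duplicatedChromosomes(cl)
    if (!nrow(d)) return(NULL)
    cbind(strainId = strainId(cl), d)
  }))
  if (is.null(dups))
    dups <- data.frame(strainId = character(), seqnames = character(),
                       multiple = numeric())
  byChrom <- as.data.frame(table(seqnames = dups$seqnames),
                           responseName = "n")
  byMult <- as.data.frame(table(seqnames = dups$seqnames,
                                multiple = dups$multiple),
                          responseName = "n")
  byMult <- byMult[byMult$n > 0, , drop = FALSE]
  rownames(byMult) <- NULL
  strains <- data.frame(
    strainId = ids, verdict = verd,
    duplicated = vapply(calls, function(cl) {
      d <- duplicatedChromosomes(cl)
      .dupString(d$seqnames, d$multiple)
    }, character(1)),
    stringsAsFactors = FALSE)
  list(n = length(calls), verdicts = c(verdicts), byChromosome = byChrom,
       byMultiple = byMult, strains = strains)
}
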