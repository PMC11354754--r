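#' @include AllClasses.R AllGenerics.R
NULL

#' Karyogamy: fuse two parental nuclei
#'
#' Element-wise sum of the parental per-chromosome copy vectors, giving the
#' fused pre-meiotic nucleus. For a dikaryon carrying one euploid and one
#' chr15-duplicated nucleus the fused nucleus has three copies of chr15 and
#' two of every other chromosome.
#'
#' @param a,b named integer copy vectors of the two nuclei (all entries
#'   >= 1, equal length).
#' @return named integer copy vector of the fused nucleus.
#' @export
#' @examples
#' a <- stats::setNames(rep(1L, 15), paste0("chr", 1:15))
#' b <- a; b["chr15"] <- 2L
#' karyogamy(a, b)["chr15"]
karyogamy <- function(a, b) {
  if (length(a) != length(b))
    stop("parental copy vectors differ in length")
  if (any(a < 1) || any(b < 1))
    stop("every nucleus must carry >= 1 copy of every chromosome")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!identical(names(a), names(b)))
      stop("parental copy vectors have different chromosome names")
  }
  k <- as.integer(a + b)
  names(k) <- if (!is.null(names(a))) names(a) else names(b)
  k
}

.pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Meiosis: allocate chromatids of a fused nucleus to four spores
#'
#' Each chromosome of the fused nucleus is replicated (2 x K_c chromatids)
#' and the chromatids are distributed over the four spores. In `faithful`
#' mode the split is as even as possible: every spore receives
#' `floor(2 K_c / 4)` chromatids and the remainder goes to a uniformly
#' random subset of spores, so a trisomic chromosome (K_c = 3, six
#' chromatids) yields two spores with one copy and two with two copies. In
#' `disordered` mode, after the faithful allocation each chromosome
#' independently suffers a nondisjunction event with probability `pNd`: one
#' chromatid moves from a random donor spore to a random other spore, which
#' can leave a spore with zero copies. Spores lacking any chromosome are
#' flagged inviable (death through chromosome loss). Chromatid conservation
#' (spore copies summing to 2 x K_c per chromosome) always holds.
#'
#' Uses the current RNG state; seed upstream (see [simulateOffspring()]).
#'
#' @param fused named integer copy vector of the fused nucleus (all >= 2),
#'   e.g. from [karyogamy()].
#' @param mode "faithful" or "disordered".
#' @param pNd per-chromosome nondisjunction probability (disordered mode).
#' @return a [SporeSet-class].
#' @export
#' @examples
#' set.seed(1)
#' k <- stats::setNames(rep(2L, 15), paste0("chr", 1:15))
#' meiose(k)             # all spores euploid and viable
meiose <- function(fused, mode = c("faithful", "disordered"), pNd = 0) {
  mode <- match.arg(mode)
  if (any(fused < 2))
    stop("fused nucleus must carry >= 2 copies of every chromosome")
  if (pNd < 0 || pNd > 1) stop("pNd must be in [0, 1]")
  nC <- length(fused)
  spores <- matrix(0L, nrow = 4L, ncol = nC,
                   dimnames = list(NULL, names(fused)))
  for (c in seq_len(nC)) {
    total <- 2L * fused[[c]]
    alloc <- rep(total %/% 4L, 4L)
    rem <- total %% 4L
    if (rem > 0L) {
      up <- sample.int(4L, rem)
      alloc[up] <- alloc[up] + 1L
    }
    if (mode == "disordered" && pNd > 0 && stats::runif(1) < pNd) {
      donor <- .pick1(which(alloc > 0L))
      recip <- .pick1(setdiff(1:4, donor))
      alloc[donor] <- alloc[donor] - 1L
      alloc[recip] <- alloc[recip] + 1L
    }
    spores[, c] <- alloc
  }
  stopifnot(all(colSums(spores) == 2L * fused))   # chromatid conservation
  new("SporeSet", spores = spores,
      viable = unname(apply(spores > 0L, 1L, all)))
}

.classLabel <- function(g) {
  dup <- g[g != 1L]
  if (!length(dup)) "euploid" else .dupString(names(dup), dup)
}

#' Simulate a cohort of viable homokaryotic offspring
#'
#' Repeats karyogamy and meiosis from a parental nucleus pair and samples
#' one uniformly chosen viable spore per meiosis until `nOffspring` viable
#' offspring are collected (offspring are i.i.d. viable spores, not
#' constrained tetrads, matching independent single-spore isolation).
#' Offspring are grouped into ploidy classes by their copy-vector signature.
#'
#' @param parentA,parentB named integer copy vectors of the parental nuclei.
#' @param nOffspring number of viable offspring to collect (>= 1).
#' @param mode,pNd allocation mode and nondisjunction probability, see
#'   [meiose()].
#' @param seed integer seed.
#' @return a [MeiosisCohort-class]; `classes` holds per-class counts,
#'   frequencies and Monte-Carlo standard errors.
#' @export
#' @examples
#' eu <- stats::setNames(rep(1L, 15), paste0("chr", 1:15))
#' an <- eu; an["chr15"] <- 2L
#' simulateOffspring(eu, an, nOffspring = 1000, seed = 1)
simulateOffspring <- function(parentA, parentB, nOffspring,
                              mode = c("faithful", "disordered"), pNd = 0,
                              seed = 1L) {
  mode <- match.arg(mode)
  if (nOffspring < 1) stop("nOffspring must be >= 1")
  fused <- karyogamy(parentA, parentB)
  set.seed(deriveSeed(seed, "meiosis"))
  offspring <- matrix(0L, nrow = nOffspring, ncol = length(fused),
                      dimnames = list(NULL, names(fused)))
  got <- 0L
  fails <- 0L
  while (got < nOffspring) {
    ss <- meiose(fused, mode = mode, pNd = pNd)
    v <- which(ss@viable)
    if (!length(v)) {
      fails <- fails + 1L
      if (fails >= 1000L)
        stop("no viable spores in 1000 consecutive meioses")
      next
    }
    fails <- 0L
    got <- got + 1L
    offspring[got, ] <- ss@spores[.pick1(v), ]
  }
  key <- apply(offspring, 1L, paste, collapse = ",")
  counts <- sort(table(key), decreasing = TRUE)
  reprs <- offspring[match(names(counts), key), , drop = FALSE]
  freq <- as.numeric(counts) / nOffspring
  classes <- data.frame(
    class = names(counts),
    label = apply(reprs, 1L, .classLabel),
    count = as.integer(counts),
    frequency = freq,
    se = sqrt(freq * (1 - freq) / nOffspring),
    stringsAsFactors = FALSE)
  rownames(classes) <- NULL
  new("MeiosisCohort", offspring = offspring, classes = classes,
      params = list(mode = mode, pNd = pNd, n = nOffspring, seed = seed,
                    fused = fused))
}

# exact multinomial test by enumeration of all outcomes of n over k classes
.exactMultinomial <- function(obs, prob) {
  n <- sum(obs)
  k <- length(prob)
  pObs <- stats::dmultinom(obs, prob = prob)
  tol <- pObs * 1e-7
  total <- 0
  rec <- function(i, left, counts) {
    if (i == k) {
      p <- stats::dmultinom(c(counts, left), prob = prob)
      if (p <= pObs + tol) total <<- total + p
      return(invisible(NULL))
    }
    for (x in 0:left) rec(i + 1L, left - x, c(counts, x))
  }
  rec(1L, n, integer())
  min(total, 1)
}

#' Compare simulated and observed offspring class distributions
#'
#' Goodness-of-fit of observed offspring class counts against the class
#' frequencies predicted by [simulateOffspring()]. Observed classes absent
#' from the simulation are pooled into an `"other"` class with expected
#' frequency zero (any observation there gives p = 0, reported as below
#' resolution). Two-class comparisons use the exact binomial test;
#' multi-class comparisons use the chi-square test when all expected counts
#' are at least 5 and an exact multinomial enumeration otherwise.
#'
#' @param simulated a [MeiosisCohort-class], or a named numeric vector of
#'   class frequencies (names are class labels such as `"euploid"`,
#'   `"chr15:2"`).
#' @param observed named vector (or table) of observed class counts.
#' @return list with `method`, `pValue` and `table` (class, observed count,
#'   expected frequency and count).
#' @export
#' @examples
#' compareCohorts(c(euploid = 0.5, "chr15:2" = 0.5),
#'                c(euploid = 5, "chr15:2" = 3))$pValue  # 0.7266
compareCohorts <- function(simulated, observed) {
  freq <- if (is(simulated, "MeiosisCohort")) {
    stats::setNames(simulated@classes$frequency, simulated@classes$label)
  } else simulated
  obs <- c(observed)
  if (is.null(names(obs)) || is.null(names(freq)))
    stop("classes must be named")
  n <- sum(obs)
  if (n == 0) stop("zero observed total")
  universe <- names(freq)
  unseen <- setdiff(names(obs), universe)
  if (length(unseen)) {
    other <- sum(obs[unseen])
    obs <- obs[setdiff(names(obs), unseen)]
    obs <- c(obs, other = other)
    freq <- c(freq, other = 0)
  }
  full <- stats::setNames(numeric(length(freq)), names(freq))
  full[names(obs)] <- obs
  obs <- full
  tab <- data.frame(class = names(freq), observed = as.numeric(obs),
                    expectedFreq = as.numeric(freq),
                    expectedCount = n * as.numeric(freq),
                    stringsAsFactors = FALSE)
  if (any(freq == 0 & obs > 0))
    return(list(
      method = "degenerate (observed class has zero expected frequency)",
      pValue = 0, table = tab))
  keep <- freq > 0
  obs <- obs[keep]; freq <- freq[keep]
  freq <- freq / sum(freq)
  if (length(freq) == 1L) {
    res <- list(method = "single-class (trivial fit)", pValue = 1)
  } else if (length(freq) == 2L) {
    bt <- stats::binom.test(obs[1L], n, p = freq[1L])
    res <- list(method = "exact binomial (two classes)",
                pValue = unname(bt$p.value))
  } else if (all(n * freq >= 5)) {
    ct <- suppressWarnings(stats::chisq.test(obs, p = freq))
    res <- list(method = "chi-square", pValue = unname(ct$p.value),
                statistic = unname(ct$statistic))
  } else {
    res <- list(method = "exact multinomial",
                pValue = .exactMultinomial(as.integer(round(obs)), freq))
  }
  res$table <- tab
  res
}
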