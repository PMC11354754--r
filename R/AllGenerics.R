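#' @include AllClasses.R
NULL

#' Accessors for KaryoDepth classes
#'
#' Small accessor generics: `strainId()` returns a strain identifier,
#' `chromLengths()` the named contig/chromosome lengths of a plan,
#' `binDepth()` the per-bin depth vector, `binSize()` the nominal bin width,
#' `binGRanges()` the underlying GRanges of a [DepthBins-class],
#' `verdict()` the strain-level ploidy verdict, `foldTable()` the
#' per-chromosome fold table, `duplicatedChromosomes()` the chromosomes with
#' assigned multiples above 1, `weightedCopies()` the nucleus-weighted mean
#' copy number per chromosome, `truthFolds()` the generator's true fold per
#' chromosome, `spores()`/`viableSpores()` the meiotic products, and
#' `cohortLabels()` the truth labels of a simulated cohort.
#'
#' @param x an object of the documented class.
#' @return see the individual generic descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))
#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setGeneric("binDepth", function(x) standardGeneric("binDepth"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("binGRanges", function(x) standardGeneric("binGRanges"))
#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @rdname accessors
#' @export
setGeneric("foldTable", function(x) standardGeneric("foldTable"))
#' @rdname accessors
#' @export
setGeneric("duplicatedChromosomes",
           function(x) standardGeneric("duplicatedChromosomes"))
#' @rdname accessors
#' @export
setGeneric("weightedCopies", function(x) standardGeneric("weightedCopies"))
#' @rdname accessors
#' @export
setGeneric("truthFolds", function(x) standardGeneric("truthFolds"))
#' @rdname accessors
#' @export
setGeneric("spores", function(x) standardGeneric("spores"))
#' @rdname accessors
#' @export
setGeneric("viableSpores", function(x) standardGeneric("viableSpores"))
#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))

#' @rdname accessors
#' @export
setMethod("strainId", "StrainConfig", function(x) x@strainId)
#' @rdname accessors
#' @export
setMethod("strainId", "KaryotypeCall", function(x) x@strainId)
#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeTruth", function(x) x@chromLengths)
#' @rdname accessors
#' @export
setMethod("binDepth", "DepthBins", function(x) x@bins$depth)
#' @rdname accessors
#' @export
setMethod("binSize", "DepthBins", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("binGRanges", "DepthBins", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("verdict", "KaryotypeCall", function(x) x@verdict)
#' @rdname accessors
#' @export
setMethod("foldTable", "KaryotypeCall", function(x) x@folds)
#' @rdname accessors
#' @export
setMethod("duplicatedChromosomes", "KaryotypeCall", function(x) x@duplicated)

#' @rdname accessors
#' @export
setMethod("weightedCopies", "StrainConfig", function(x) {
  drop(x@weights %*% x@copies)
})

#' @rdname accessors
#' @export
setMethod("truthFolds", "StrainConfig", function(x) {
  m <- weightedCopies(x)
  m / stats::median(m)
})

#' @rdname accessors
#' @export
setMethod("spores", "SporeSet", function(x) x@spores)
#' @rdname accessors
#' @export
setMethod("viableSpores", "SporeSet", function(x) x@viable)
#' @rdname accessors
#' @export
setMethod("cohortLabels", "CohortTruth", function(x) x@labels)

#' Coerce DepthBins to a data.frame
#'
#' Returns the 0-based half-open bin table (`sequence`, `start`, `end`,
#' `depth`), the on-disk TSV layout used by [writeDepthTable()].
#'
#' @param x a [DepthBins-class].
#' @param ... ignored.
#' @return data.frame with one row per bin.
#' @export
#' @method as.data.frame DepthBins
as.data.frame.DepthBins <- function(x, ...) {
  gr <- x@bins
  data.frame(
    sequence = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    depth = gr$depth,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "GenomeTruth", function(object) {
  cat(sprintf("GenomeTruth: %d contigs, %.2f Mb total\n",
              length(object@chromLengths), sum(object@chromLengths) / 1e6))
  cat(sprintf("  telomere plan: %d terminal arrays; rDNA plan: %d arrays\n",
              nrow(object@telomerePlan), nrow(object@rdnaPlan)))
})

setMethod("show", "StrainConfig", function(object) {
  cat(sprintf("StrainConfig '%s': %d nucleus genotype(s), %d chromosomes\n",
              object@strainId, nrow(object@copies), ncol(object@copies)))
  cat(sprintf("  base depth %gx, NB dispersion %g, outliers %.1f%% in [%g, %g]\n",
              object@baseDepth, object@dispersion,
              100 * object@outlierFraction,
              object@outlierRange[1], object@outlierRange[2]))
  tf <- truthFolds(object)
  off <- tf[abs(tf - 1) > 1e-9]
  if (length(off))
    cat("  true folds != 1:",
        paste(sprintf("%s=%g", names(off), off), collapse = ", "), "\n")
  else cat("  euploid (all true folds 1)\n")
})

setMethod("show", "DepthBins", function(object) {
  gr <- object@bins
  cat(sprintf("DepthBins: %d bins (%d bp) on %d sequences [source: %s]\n",
              length(gr), object@binSize,
              length(unique(GenomeInfoDb::seqnames(gr))), object@source))
  cat(sprintf("  depth: median %.1f, range [%.1f, %.1f]\n",
              stats::median(gr$depth), min(gr$depth), max(gr$depth)))
})

setMethod("show", "KaryotypeCall", function(object) {
  cat(sprintf("KaryotypeCall '%s': %s (baseline %.1fx)\n",
              object@strainId, object@verdict, object@baseline))
  d <- object@duplicated
  if (nrow(d))
    cat("  duplicated:",
        paste(sprintf("%s at %gx", d$seqnames, d$multiple), collapse = ", "),
        "\n")
  un <- sum(is.na(object@folds$multiple))
  if (un) cat(sprintf("  %d chromosome(s) unassigned\n", un))
})

setMethod("show", "NucleusMixture", function(object) {
  if (!object@feasible) {
    cat("NucleusMixture: infeasible —", object@note, "\n")
    return(invisible(NULL))
  }
  cat(sprintf("NucleusMixture (%d nuclei/cell): %d distinct genotype(s)\n",
              object@nucleusCount, nrow(object@genotypes)))
  for (i in seq_len(nrow(object@genotypes))) {
    g <- object@genotypes[i, ]
    dup <- g[g != 1]
    desc <- if (length(dup))
      paste(sprintf("%s=%d", names(dup), dup), collapse = ", ")
    else "euploid"
    cat(sprintf("  w=%.3g: %s\n", object@weights[i], desc))
  }
})

setMethod("show", "CohortTruth", function(object) {
  tab <- table(object@labels$verdict)
  cat(sprintf("CohortTruth: %d offspring of '%s' (%s)\n",
              length(object@configs), object@parent@strainId,
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
})

setMethod("show", "SporeSet", function(object) {
  cat(sprintf("SporeSet: %d/4 viable spores\n", sum(object@viable)))
})

setMethod("show", "MeiosisCohort", function(object) {
  cat(sprintf("MeiosisCohort: %d viable offspring (%s mode), %d classes\n",
              nrow(object@offspring), object@params$mode,
              nrow(object@classes)))
  cl <- object@classes
  for (i in seq_len(min(nrow(cl), 8L)))
    cat(sprintf("  %-28s %5d  (%.3f +/- %.3f)\n",
                cl$label[i], cl$count[i], cl$frequency[i], cl$se[i]))
})
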