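#' @include AllClasses.R synthetic-assembly.R synthetic-depth.R
#' @include assembly-scan.R depth-profile.R ploidy-call.R meiosis-model.R
NULL

.atomicWrite <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

.strainFromSpec <- function(spec, seed) {
  if (is.character(spec) && length(spec) == 1L)
    return(exampleStrain(spec, seed = seed))
  if (!is.null(spec$name)) {
    args <- spec[setdiff(names(spec), "name")]
    args$name <- spec$name
    if (is.null(args$seed)) args$seed <- seed
    return(do.call(exampleStrain, args))
  }
  copies <- do.call(rbind, lapply(spec$copies, function(v) unlist(v)))
  strainConfig(spec$strainId, copies, weights = spec$weights,
               baseDepth = spec$baseDepth %||% 50,
               dispersion = spec$dispersion %||% 0.1,
               outlierFraction = spec$outlierFraction %||% 0.02,
               seed = spec$seed %||% seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.planFromSpec <- function(spec) {
  builder <- switch(spec$plan %||% "L7",
                    L7 = l7AssemblyPlan,
                    Pr2C = pr2cAssemblyPlan,
                    PrT = prtAssemblyPlan,
                    stop("unknown assembly plan: ", spec$plan))
  args <- spec[intersect(names(spec), names(formals(builder)))]
  do.call(builder, args)
}

#' Run the end-to-end karyotype pipeline
#'
#' Orchestrates the stages configured in `config`: synthetic assembly
#' generation plus telomere/rDNA scan and chromosome accounting
#' (`config$assembly`), depth simulation plus fold classification
#' (`config$strain`, with optional `config$depth` and `config$call`
#' settings), and the meiosis simulator (`config$meiosis`). Every stage
#' seeds its randomness from `config$seed` via [deriveSeed()], so stages are
#' independently reproducible and identical config + seed give identical
#' artifacts. Artifacts (FASTA, BED, TSV, JSON and a human-readable
#' `report.txt` restating the calls) are written atomically to `outDir`
#' together with `provenance.json` (seed, config hash, package version).
#'
#' @param config a list or path to a JSON file. Fields: `seed` (required),
#'   `assembly` (list: `plan` = "L7"/"Pr2C"/"PrT" and plan arguments),
#'   `strain` (an [exampleStrain()] name or a full strain spec), `depth`
#'   (list: `binSize`), `call` (list: `grid`, `tolerance`, `bootstrapReps`),
#'   `meiosis` (list: `parentA`, `parentB` named copy vectors, `mode`,
#'   `pNd`, `n`, optional `observed` counts).
#' @param outDir output directory (default `config$out`); created if needed.
#' @return invisibly, a list with the stage results and artifact paths.
#' @export
#' @examples
#' \donttest{
#' out <- tempfile("run")
#' res <- runPipeline(list(seed = 1, strain = "L7", out = out))
#' readLines(file.path(out, "report.txt"))
#' }
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config) || is.null(config$seed))
    stop("usage: config must be a list (or JSON file) with at least a ",
         "'seed' and one stage ('assembly', 'strain' or 'meiosis')")
  if (!any(c("assembly", "strain", "meiosis") %in% names(config)))
    stop("usage: no stage configured; provide 'assembly', 'strain' or ",
         "'meiosis'")
  outDir <- outDir %||% config$out %||% stop("no output directory given")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  artifacts <- character()
  report <- c("KaryoDepth pipeline report", sprintf("seed: %d", seed), "")
  results <- list()

  if (!is.null(config$assembly)) {
    plan <- .planFromSpec(config$assembly)
    asm <- generateAssembly(plan, seed = deriveSeed(seed, "stage/assembly"))
    fa <- file.path(outDir, "assembly.fasta")
    .atomicWrite(function(p) Biostrings::writeXStringSet(asm$sequences, p), fa)
    scan <- scanAssembly(asm$sequences)
    bed <- file.path(outDir, "features.bed")
    feats <- rbind(
      data.frame(contig = scan$telomeres$contig,
                 start = scan$telomeres$start, end = scan$telomeres$end,
                 name = paste0("telomere_", scan$telomeres$side),
                 score = scan$telomeres$copies,
                 strand = scan$telomeres$strand),
      if (nrow(scan$rdna)) data.frame(
        contig = scan$rdna$contig, start = scan$rdna$start,
        end = scan$rdna$end, name = "rdna",
        score = round(scan$rdna$identity), strand = scan$rdna$strand)
      else NULL)
    .atomicWrite(function(p) utils::write.table(
      feats, p, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE), bed)
    accJson <- file.path(outDir, "accounting.json")
    .atomicWrite(function(p) .writeJson(scan$accounting, p), accJson)
    acc <- scan$accounting
    report <- c(report,
      sprintf("Assembly: %d contigs; %d with double-sided telomeres, %d with a single telomere plus terminal rDNA.",
              acc$n_contigs, acc$n_double_sided, acc$n_single_plus_rdna),
      sprintf("Predicted chromosome number: %d (strict %d).",
              acc$chromosome_count_extended, acc$chromosome_count_strict), "")
    artifacts <- c(artifacts, fa, bed, accJson)
    results$assembly <- scan
  }

  if (!is.null(config$strain)) {
    strain <- .strainFromSpec(config$strain, seed = seed)
    binSize <- config$depth$binSize %||% 10000
    truth <- referenceChromosomeLengths()
    sim <- simulateDepth(truth, strain, binSize = binSize,
                         seed = deriveSeed(seed, "stage/depth"))
    tsv <- file.path(outDir, "depth_bins.tsv")
    .atomicWrite(function(p) writeDepthTable(sim$bins, p), tsv)
    callCfg <- config$call %||% list()
    call <- classifyFolds(sim$bins, strainId = strain@strainId,
                          grid = callCfg$grid %||% defaultFoldGrid(),
                          tolerance = callCfg$tolerance %||% 0.12,
                          bootstrapReps = callCfg$bootstrapReps %||% 200,
                          seed = deriveSeed(seed, "stage/call"))
    callJson <- file.path(outDir, "karyotype_call.json")
    .atomicWrite(function(p) .writeJson(list(
      strainId = strainId(call), verdict = verdict(call),
      baseline = call@baseline, grid = call@grid,
      tolerance = call@tolerance, folds = foldTable(call)), p), callJson)
    report <- c(report, sprintf("Strain %s: verdict %s (baseline %.1fx).",
                                strainId(call), verdict(call),
                                call@baseline))
    d <- duplicatedChromosomes(call)
    for (i in seq_len(nrow(d)))
      report <- c(report, sprintf(
        "Chromosome %s has %gx (fold) sequencing depth compared to other chromosomes.",
        d$seqnames[i], d$multiple[i]))
    report <- c(report, "")
    artifacts <- c(artifacts, tsv, callJson)
    results$call <- call
  }

  if (!is.null(config$meiosis)) {
    mc <- config$meiosis
    cohort <- simulateOffspring(unlist(mc$parentA), unlist(mc$parentB),
                                nOffspring = mc$n %||% 10000,
                                mode = mc$mode %||% "faithful",
                                pNd = mc$pNd %||% 0,
                                seed = deriveSeed(seed, "stage/meiosis"))
    clsTsv <- file.path(outDir, "meiosis_classes.tsv")
    .atomicWrite(function(p) utils::write.table(
      cohort@classes, p, sep = "\t", quote = FALSE, row.names = FALSE),
      clsTsv)
    artifacts <- c(artifacts, clsTsv)
    report <- c(report, sprintf(
      "Meiosis (%s mode): %d offspring classes among %d viable spores.",
      cohort@params$mode, nrow(cohort@classes), nrow(cohort@offspring)))
    if (!is.null(mc$observed)) {
      fit <- compareCohorts(cohort, unlist(mc$observed))
      fitJson <- file.path(outDir, "cohort_fit.json")
      .atomicWrite(function(p) .writeJson(fit, p), fitJson)
      artifacts <- c(artifacts, fitJson)
      report <- c(report, sprintf("Cohort fit: %s, p = %.4g.",
                                  fit$method, fit$pValue))
      results$fit <- fit
    }
    report <- c(report, "")
    results$meiosis <- cohort
  }

  cfgJson <- file.path(outDir, "config.json")
  .atomicWrite(function(p) .writeJson(config, p), cfgJson)
  prov <- list(
    seed = seed,
    configHash = unname(tools::md5sum(cfgJson)),
    package = "KaryoDepth",
    version = as.character(utils::packageVersion("KaryoDepth")))
  provJson <- file.path(outDir, "provenance.json")
  .atomicWrite(function(p) .writeJson(prov, p), provJson)
  repTxt <- file.path(outDir, "report.txt")
  .atomicWrite(function(p) writeLines(report, p), repTxt)
  artifacts <- c(artifacts, cfgJson, provJson, repTxt)
  results$artifacts <- artifacts
  results$report <- report
  invisible(results)
}
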