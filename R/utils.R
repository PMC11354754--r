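#' Derive a stage seed from a global seed
#'
#' One global seed fans out to per-stage (or per-strain, per-target) seeds so
#' pipeline stages are independently reproducible. The derivation is a fixed
#' integer hash of the label folded into the seed, kept below 2^31.
#'
#' @param seed integer global seed.
#' @param label character label of the stage / sub-task.
#' @return a single integer seed in [0, 2^31 - 1].
#' @export
#' @examples
#' deriveSeed(1, "depth")
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (v in utf8ToInt(paste(label, collapse = "/")))
    h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) + 7919 * h) %% 2147483647)
}

# trimmed mean that tolerates empty input with a clear error
.trimmedMean <- function(x, trim) {
  if (!length(x)) stop("no values to summarize")
  mean(x, trim = trim)
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

# format a duplication table as the field writes it: "chr15:2"
.dupString <- function(seqnames, multiple) {
  if (!length(seqnames)) return("")
  paste(sprintf("%s:%g", seqnames, multiple), collapse = ",")
}
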