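## Internal helpers shared across modules.

#' @importFrom withr with_seed
.withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

## Derive a stream of child seeds from one master seed, so that independent
## stages draw from independent, reproducible streams. Kept below 2^31.
.childSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Median over non-missing values
#'
#' Region-level summary used throughout the framework: the median of the
#' non-missing per-variant values, with the usual mean-of-central-pair rule
#' for even counts. Returns `NA` when every value is missing.
#'
#' @param values Numeric vector, possibly containing `NA`.
#' @return A single numeric value, or `NA` if no value is non-missing.
#' @export
regionMedian <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) return(NA_real_)
  stats::median(v)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readTsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, ...)
}
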