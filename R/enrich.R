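## Set-level enrichment of evolutionary signatures over all trait regions,
## against the genome-wide background and against matched nulls.

#' Genome-wide enrichment of trait-region medians for one measure
#'
#' Per iteration, samples `n_random` random-region medians from the pool,
#' takes their 95th percentile, and counts trait regions with median at or
#' above it; reports the mean and the 5th/95th percentiles of the counts
#' over `n_iter` iterations. The analytic null expectation is a 5% success
#' rate over the trait regions (Binomial), and the binomial p is
#' P(X >= round(mean count)) for X ~ Binomial(#regions, rate).
#'
#' @param trait_medians Observed trait-region medians (one per region).
#' @param pool_medians Pool of random-region medians (size >= `n_random`).
#' @param n_random Random regions drawn per iteration (default 5000).
#' @param n_iter Iterations (default 1000).
#' @param seed Integer seed.
#' @param rate Tail rate defining the percentile and the Binomial null
#'   (default 0.05).
#' @return One-row `data.frame`: `observed_count` (mean over iterations),
#'   `null_q05`, `null_q95`, `binomial_expected`, `binomial_p`, `n_regions`.
#' @export
genomewideEnrichment <- function(trait_medians, pool_medians,
                                 n_random = 5000L, n_iter = 1000L, seed,
                                 rate = 0.05) {
  trait_medians <- trait_medians[!is.na(trait_medians)]
  pool_medians <- pool_medians[!is.na(pool_medians)]
  if (length(pool_medians) < n_random)
    stop("pool smaller than n_random (", length(pool_medians), " < ",
         n_random, ")")
  n_regions <- length(trait_medians)
  counts <- .withSeed(seed, vapply(seq_len(n_iter), function(i) {
    cut <- stats::quantile(sample(pool_medians, n_random), 1 - rate,
                           names = FALSE)
    sum(trait_medians >= cut)
  }, numeric(1L)))
  mean_count <- mean(counts)
  expected <- rate * n_regions
  p <- stats::pbinom(round(mean_count) - 1L, n_regions, rate,
                     lower.tail = FALSE)
  data.frame(observed_count = mean_count,
             null_q05 = stats::quantile(counts, 0.05, names = FALSE),
             null_q95 = stats::quantile(counts, 0.95, names = FALSE),
             binomial_expected = expected, binomial_p = p,
             n_regions = n_regions)
}

#' Binomial null expectation for the significant-region count
#'
#' Expected number of regions in the top tail by chance, and the Binomial
#' survival probability of an observed count.
#'
#' @param n_regions Number of trait regions (215 in the full-scale design).
#' @param observed_count Observed significant-region count (optional).
#' @param rate Success rate (default 0.05).
#' @return List with `expected` (= rate * n_regions) and, when
#'   `observed_count` is given, `p` = P(X >= observed_count).
#' @export
binomialNull <- function(n_regions, observed_count = NULL, rate = 0.05) {
  out <- list(expected = rate * n_regions)
  if (!is.null(observed_count))
    out$p <- stats::pbinom(observed_count - 1L, n_regions, rate,
                           lower.tail = FALSE)
  out
}

#' Matched-null enrichment of significant trait regions for one measure
#'
#' The observed count is the number of trait regions with empirical
#' p < `alpha` against their own matched controls. The null is built by
#' evaluating `n_iter` random region sets of equal size against their own
#' matched controls (via `null_generator`) and counting p < `alpha` in
#' each; enrichment is flagged when the observed count exceeds the null's
#' 95th percentile.
#'
#' @param trait_p Empirical p-values of the trait regions (NA allowed;
#'   NA never counts as significant).
#' @param null_generator Function of one integer seed returning the
#'   empirical p-values of one random region set evaluated against its own
#'   matched controls.
#' @param n_iter Null iterations (default 1000).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Integer seed.
#' @return One-row `data.frame`: `observed_count`, `null_mean`, `null_q05`,
#'   `null_q95`, `flagged`.
#' @export
matchedEnrichment <- function(trait_p, null_generator, n_iter = 1000L,
                              alpha = 0.05, seed) {
  observed <- sum(trait_p < alpha, na.rm = TRUE)
  seeds <- .childSeeds(seed, n_iter)
  null_counts <- vapply(seq_len(n_iter), function(i) {
    p <- null_generator(seeds[i])
    sum(p < alpha, na.rm = TRUE)
  }, numeric(1L))
  q95 <- stats::quantile(null_counts, 0.95, names = FALSE)
  data.frame(observed_count = observed, null_mean = mean(null_counts),
             null_q05 = stats::quantile(null_counts, 0.05, names = FALSE),
             null_q95 = q95, flagged = observed > q95)
}
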