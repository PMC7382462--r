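## Per-region empirical p-values and z-scores against the matched-control
## null: control marking/removal bookkeeping, the count-based p, and the
## region x measure evaluation loop.

#' Build the matched-control null for one region x measure
#'
#' For each control region, a member counts as matched when its slot is
#' filled with a real variant AND that variant has a non-missing value for
#' this measure. Controls matching fewer than 90% of the trait region's
#' variants are marked and excluded from the null; the remaining controls
#' contribute the median of their members' values. When at least 60% of
#' controls are marked the region is removed for this measure.
#'
#' @param suite A [ControlSuite-class].
#' @param track A [ScoreTrack-class] for the measure.
#' @param panel [HaplotypePanel-class] giving member coordinates.
#' @param transform `"identity"` or `"abs"`, applied to values before
#'   medians (see [defaultMeasureRegistry()]).
#' @param mark_below Controls matching less than this fraction are marked
#'   (default 0.90; a fraction of exactly 0.90 passes).
#' @param remove_at Region removed when marked fraction >= this (default
#'   0.60, inclusive).
#' @return A [NullDistribution-class].
#' @export
buildNull <- function(suite, track, panel, transform = "identity",
                      mark_below = 0.90, remove_at = 0.60) {
  m <- suite@members
  if (nrow(m) == 0L) {
    ## no matched controls at all: the region is unevaluable, i.e. removed
    return(new("NullDistribution", regionId = suite@regionId,
               measureName = measureName(track),
               controlMedians = numeric(), nMarked = 0L, nUsed = 0L,
               removed = TRUE))
  }
  v <- variantInfo(panel)
  vi <- match(m$member_id, v$id)
  vals <- rep(NA_real_, nrow(m))
  has <- !is.na(vi)
  vals[has] <- trackLookup(track, v$chrom[vi[has]], v$pos[vi[has]])
  vals <- .applyTransform(vals, transform)

  size <- suite@regionSize
  by_ctl <- split(vals, m$control_index)
  matched <- vapply(by_ctl, function(x) sum(!is.na(x)), integer(1L))
  frac <- matched / size
  marked <- frac < mark_below
  medians <- vapply(by_ctl[!marked], regionMedian, numeric(1L))
  medians <- medians[!is.na(medians)]
  n_total <- length(by_ctl)
  removed <- n_total == 0L || (sum(marked) / n_total) >= remove_at
  new("NullDistribution", regionId = suite@regionId,
      measureName = measureName(track),
      controlMedians = unname(medians),
      nMarked = as.integer(sum(marked)),
      nUsed = length(medians), removed = removed)
}

#' Empirical p-value of an observed region median
#'
#' Count rule against the matched null: upper tail,
#' p = #\{control medians >= observed\} / n_used; two-sided, twice the
#' smaller tail count (ties count in both tails), capped at 1. p = 0 is
#' reported as produced by the count rule, with `nUsed` available so users
#' can floor at 1/n_used. Fewer usable controls than `min_controls` yields
#' `NA` (logged).
#'
#' @param observed Observed trait-region median.
#' @param null A [NullDistribution-class]; must not be removed.
#' @param tail `"upper"` or `"two_sided"`.
#' @param min_controls Minimum usable controls for a valid p (default 100).
#' @return p in `[0, 1]`, or `NA`.
#' @export
empiricalP <- function(observed, null, tail = c("upper", "two_sided"),
                       min_controls = 100L) {
  tail <- match.arg(tail)
  if (null@removed) stop("region removed for this measure: no p-value")
  n <- null@nUsed
  if (n < min_controls) {
    message("empiricalP: only ", n, " usable controls for region ",
            null@regionId, " x ", null@measureName)
    return(NA_real_)
  }
  cm <- null@controlMedians
  if (tail == "upper") sum(cm >= observed) / n
  else min(1, 2 * min(sum(cm >= observed), sum(cm <= observed)) / n)
}

#' Z-score of an observed region median against the matched null
#'
#' (observed - mean(control medians)) / sd(control medians), sd with the
#' n - 1 denominator. Zero sd yields `NA` (logged).
#'
#' @inheritParams empiricalP
#' @return Numeric z, or `NA`.
#' @export
zScore <- function(observed, null) {
  cm <- null@controlMedians
  if (length(cm) < 2L) return(NA_real_)
  sdv <- stats::sd(cm)
  if (sdv == 0) {
    message("zScore: zero control sd for region ", null@regionId,
            " x ", null@measureName)
    return(NA_real_)
  }
  (observed - mean(cm)) / sdv
}

#' Evaluate every region against every measure
#'
#' One result row per region x measure, carrying the observed median, null
#' bookkeeping, empirical p and z, with removed and missing states explicit.
#' Deterministic given its inputs.
#'
#' @param regions Region table from [clumpRegions()].
#' @param suites Named list of [ControlSuite-class], keyed by region id;
#'   a region without a suite is an error.
#' @param tracks Named list of [ScoreTrack-class], keyed by measure name.
#' @param registry Measure registry (see [defaultMeasureRegistry()]); only
#'   registry measures present in `tracks` are evaluated.
#' @param panel [HaplotypePanel-class] giving member coordinates.
#' @param min_controls Minimum usable controls for a valid p.
#' @return `data.frame`: `region_id`, `measure`, `observed_median`,
#'   `n_used`, `n_marked`, `p`, `z`, `removed`.
#' @export
evaluateAll <- function(regions, suites, tracks,
                        registry = defaultMeasureRegistry(), panel,
                        min_controls = 100L) {
  rl <- regionList(regions)
  missing_suite <- setdiff(names(rl), names(suites))
  if (length(missing_suite))
    stop("region without control suite: ", missing_suite[[1L]])
  measures <- intersect(registry$measure, names(tracks))
  rows <- list()
  for (rid in names(rl)) {
    region <- rl[[rid]]
    for (ms in measures) {
      reg <- registry[registry$measure == ms, ]
      track <- tracks[[ms]]
      vals <- .applyTransform(lookupTrackValues(track, region),
                              reg$transform)
      obs <- regionMedian(vals)
      null <- buildNull(suites[[rid]], track, panel,
                        transform = reg$transform)
      p <- NA_real_; z <- NA_real_
      if (!null@removed && !is.na(obs)) {
        p <- suppressMessages(
          empiricalP(obs, null, tail = reg$tail,
                     min_controls = min_controls))
        z <- suppressMessages(zScore(obs, null))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = rid, measure = ms, observed_median = obs,
        n_used = null@nUsed, n_marked = null@nMarked, p = p, z = z,
        removed = null@removed, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
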