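## Clustering of regions by z-score signature and the extreme-signature
## filter (|z| >= 1.5 on at least one measure).

#' Build the region x measure z matrix
#'
#' Measures with z missing in more than `max_missing_fraction` of regions
#' are dropped (logged) — this is the rule that excludes measures with
#' pervasive missingness, as iHS often is. Remaining missing cells are
#' imputed to 0 for clustering geometry only, with the imputation mask
#' recorded.
#'
#' @param results [evaluateAll()] output.
#' @param max_missing_fraction Drop threshold (default 0.5, strict: a
#'   measure is dropped when missing in strictly more than this fraction).
#' @return A [ZMatrix-class].
#' @export
buildZMatrix <- function(results, max_missing_fraction = 0.5) {
  regions <- unique(results$region_id)
  measures <- unique(results$measure)
  z <- matrix(NA_real_, length(regions), length(measures),
              dimnames = list(regions, measures))
  z[cbind(match(results$region_id, regions),
          match(results$measure, measures))] <- results$z
  miss_frac <- colMeans(is.na(z))
  drop <- miss_frac > max_missing_fraction
  if (any(drop))
    message("buildZMatrix: dropped measure(s) for missingness: ",
            paste(measures[drop], collapse = ", "))
  if (all(drop)) stop("all measures dropped for missingness")
  z <- z[, !drop, drop = FALSE]
  mask <- is.na(z)
  z[mask] <- 0
  new("ZMatrix", z = z, mask = mask,
      droppedMeasures = measures[drop])
}

#' Regions with at least one extreme z-score
#'
#' Regions whose maximum |z| over unimputed entries reaches `threshold`;
#' imputed cells never qualify.
#'
#' @param zm A [ZMatrix-class].
#' @param threshold |z| threshold (default 1.5).
#' @return Character vector of region ids.
#' @export
extremeRegions <- function(zm, threshold = 1.5) {
  z <- zm@z
  z[zm@mask] <- 0
  hit <- apply(abs(z) >= threshold & !zm@mask, 1L, any)
  rownames(z)[hit]
}

#' Hierarchically cluster regions by z signature
#'
#' Agglomerative clustering of z-matrix rows (Euclidean distance, complete
#' linkage by default), with the dendrogram cut at `cut_height` (the
#' branch-length cutoff). Labels are renumbered by first region occurrence
#' so the partition is deterministic and invariant to row permutation.
#'
#' @param zm A [ZMatrix-class].
#' @param cut_height Dendrogram cut height (default 7).
#' @param method Linkage for [stats::hclust()] (default `"complete"`).
#' @return Named integer vector of cluster labels per region.
#' @export
clusterRegions <- function(zm, cut_height = 7.0, method = "complete") {
  z <- zm@z
  if (nrow(z) == 1L || !is.finite(cut_height)) {
    lab <- rep(1L, nrow(z))
    names(lab) <- rownames(z)
    return(lab)
  }
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = method)
  raw <- stats::cutree(hc, h = cut_height)
  ## renumber by first occurrence in the input row order
  lev <- unique(raw)
  lab <- match(raw, lev)
  names(lab) <- rownames(z)
  lab
}

#' Heatmap of the z matrix
#'
#' @param zm A [ZMatrix-class].
#' @param file Optional PNG path; plots to the active device otherwise.
#' @param ... Passed to [stats::heatmap()].
#' @return Invisibly, `NULL`.
#' @export
plotZHeatmap <- function(zm, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  stats::heatmap(zm@z, scale = "none", ...)
  invisible(NULL)
}
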