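## MAF / LD / gene-architecture matched control regions: annotate the panel
## variant pool with the four matching covariates, select matched control
## leads per trait region, and assemble control regions by two-pass LD fill.

#' Precompute per-chromosome r-squared matrices
#'
#' One-off LD cache for a panel; all buddy counting and partner lookup reads
#' from it. Memory is quadratic per chromosome, so panels are expected to be
#' split over several chromosomes.
#'
#' @param panel A [HaplotypePanel-class].
#' @return An opaque cache object for [annotatePool()] and
#'   [assembleControlRegions()].
#' @export
ldCache <- function(panel) {
  v <- variantInfo(panel)
  H <- haplotypes(panel)
  by_chrom <- split(seq_len(nrow(v)), v$chrom)
  cache <- lapply(by_chrom, function(idx) {
    list(idx = idx, pos = v$pos[idx], r2 = .r2Matrix(H[, idx, drop = FALSE]))
  })
  structure(list(chroms = cache, variant_id = v$id, chrom = v$chrom,
                 pos = v$pos), class = "evoregLdCache")
}

## Partners of global column i: global indices with |pos diff| <= window_bp
## and r2 > threshold (self excluded), plus their r2 values.
.ldPartners <- function(cache, i, window_bp, threshold) {
  ch <- cache$chroms[[cache$chrom[i]]]
  local_i <- match(i, ch$idx)
  in_win <- which(abs(ch$pos - ch$pos[local_i]) <= window_bp)
  in_win <- setdiff(in_win, local_i)
  r2 <- ch$r2[local_i, in_win]
  keep <- !is.na(r2) & r2 > threshold
  list(idx = ch$idx[in_win[keep]], r2 = r2[keep])
}

#' Annotate the variant pool with matching covariates
#'
#' For every polymorphic panel variant: minor allele frequency (folded),
#' number of LD buddies (panel variants within `buddy_window_bp` at
#' `r^2 > buddy_r2`, self excluded), gene density (genes overlapping a
#' window of `density_window_bp` centered on the variant) and distance in bp
#' to the nearest gene (0 if genic).
#'
#' @param panel A [HaplotypePanel-class].
#' @param genes `GRanges` of gene intervals (see [readGeneBed()]).
#' @param density_window_bp Width of the centered gene-density window.
#' @param buddy_window_bp,buddy_r2 LD-buddy window and threshold.
#' @param cache Optional [ldCache()] for the panel.
#' @return `data.frame` with `variant_id`, `chrom`, `pos`, `maf`,
#'   `n_ld_buddies`, `gene_density`, `gene_distance`.
#' @export
annotatePool <- function(panel, genes, density_window_bp = 100000L,
                         buddy_window_bp = 250000L, buddy_r2 = 0.9,
                         cache = NULL) {
  if (length(genes) == 0L) stop("empty gene set: gene distance undefined")
  v <- variantInfo(panel)
  H <- haplotypes(panel)
  freq <- colMeans(H)
  poly <- freq > 0 & freq < 1
  if (any(!poly))
    message("annotatePool: excluded ", sum(!poly),
            " monomorphic variant(s)")
  if (is.null(cache)) cache <- ldCache(panel)

  keep <- which(poly)
  buddies <- vapply(keep, function(i) {
    length(.ldPartners(cache, i, buddy_window_bp, buddy_r2)$idx)
  }, integer(1L))

  pts <- GenomicRanges::GRanges(v$chrom[keep],
                                IRanges::IRanges(v$pos[keep], v$pos[keep]))
  half <- as.integer(density_window_bp / 2L)
  win <- GenomicRanges::GRanges(
    v$chrom[keep],
    IRanges::IRanges(pmax(1L, v$pos[keep] - half), v$pos[keep] + half))
  density <- GenomicRanges::countOverlaps(win, genes, ignore.strand = TRUE)
  hits <- GenomicRanges::distanceToNearest(pts, genes, ignore.strand = TRUE)
  dist <- rep(NA_integer_, length(pts))
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance

  data.frame(variant_id = v$id[keep], chrom = v$chrom[keep],
             pos = v$pos[keep], maf = pmin(freq[keep], 1 - freq[keep]),
             n_ld_buddies = buddies, gene_density = as.integer(density),
             gene_distance = as.integer(dist), stringsAsFactors = FALSE,
             row.names = NULL)
}

## relative window [max(0, x(1-rel)), x(1+rel)]; degenerate at x = 0.
.inRelWindow <- function(candidate, center, rel) {
  candidate >= pmax(0, center * (1 - rel)) & candidate <= center * (1 + rel)
}

#' Select matched control lead variants
#'
#' Candidates must satisfy all four matching windows relative to the trait
#' lead: MAF within +/-0.05 (absolute percentage points), LD-buddy count
#' within +/-10% (relative), gene density and gene distance within +/-500%
#' (relative, lower bound clipped at 0). The trait region's own members and
#' any pool variant within `exclude_window_bp` of the lead are excluded. If
#' more than `n` candidates qualify, `n` are sampled without replacement
#' under `seed`; if fewer, all are returned and the shortfall is logged.
#'
#' @param lead_ann One-row annotation `data.frame` for the trait lead (a row
#'   of [annotatePool()] output).
#' @param pool Annotation `data.frame` for the candidate pool.
#' @param n Number of control leads requested.
#' @param seed Integer seed for sampling.
#' @param exclude_ids Variant ids to exclude (the trait region's members).
#' @param exclude_window_bp Exclusion window around the trait lead.
#' @param maf_tol,buddy_rel,gene_rel Matching tolerances.
#' @return Character vector of control lead variant ids.
#' @export
selectControlLeads <- function(lead_ann, pool, n, seed,
                               exclude_ids = character(),
                               exclude_window_bp = 250000L,
                               maf_tol = 0.05, buddy_rel = 0.10,
                               gene_rel = 5.0) {
  if (nrow(pool) == 0L) stop("empty control pool")
  near_lead <- pool$chrom == lead_ann$chrom &
    abs(pool$pos - lead_ann$pos) <= exclude_window_bp
  ok <- !(pool$variant_id %in% c(exclude_ids, lead_ann$variant_id)) &
    !near_lead &
    abs(pool$maf - lead_ann$maf) <= maf_tol &
    .inRelWindow(pool$n_ld_buddies, lead_ann$n_ld_buddies, buddy_rel) &
    .inRelWindow(pool$gene_density, lead_ann$gene_density, gene_rel) &
    .inRelWindow(pool$gene_distance, lead_ann$gene_distance, gene_rel)
  ok[is.na(ok)] <- FALSE
  cand <- pool$variant_id[ok]
  if (length(cand) <= n) {
    if (length(cand) < n)
      message("selectControlLeads: only ", length(cand), " of ", n,
              " matched candidates for lead ", lead_ann$variant_id)
    return(cand)
  }
  .withSeed(seed, sample(cand, n))
}

#' Assemble LD partner sets for control leads
#'
#' For each control lead, samples `k` distinct partner variants with
#' `r^2 > 0.9` to the lead within the clump window; unfilled slots are
#' refilled from partners at `r^2 > 0.6`; slots still unfilled become
#' missing members. The structural match fraction (filled slots incl. lead
#' over trait-region size `k + 1`) is recorded per control region.
#'
#' @param region_id Trait region id the suite belongs to.
#' @param control_leads Character vector of control lead variant ids.
#' @param k Partners per control = trait region size - 1.
#' @param panel A [HaplotypePanel-class].
#' @param seed Integer seed for partner sampling.
#' @param window_bp Partner search window around the control lead.
#' @param r2_strict,r2_relaxed The two-pass LD thresholds.
#' @param cache Optional [ldCache()] for the panel.
#' @param n_requested Bookkeeping: controls originally requested.
#' @return A [ControlSuite-class].
#' @export
assembleControlRegions <- function(region_id, control_leads, k, panel, seed,
                                   window_bp = 250000L, r2_strict = 0.9,
                                   r2_relaxed = 0.6, cache = NULL,
                                   n_requested = length(control_leads)) {
  if (is.null(cache)) cache <- ldCache(panel)
  v <- variantInfo(panel)
  lead_cols <- match(control_leads, v$id)
  if (anyNA(lead_cols))
    stop("control lead absent from panel: ",
         control_leads[which(is.na(lead_cols))[1L]])
  rows <- .withSeed(seed, lapply(seq_along(control_leads), function(ci) {
    i <- lead_cols[ci]
    strict <- .ldPartners(cache, i, window_bp, r2_strict)
    pick <- if (length(strict$idx) <= k) strict$idx else
      sample(strict$idx, k)
    tier <- rep("0.9", length(pick))
    short <- k - length(pick)
    if (short > 0L) {
      relaxed <- .ldPartners(cache, i, window_bp, r2_relaxed)
      pool2 <- setdiff(relaxed$idx, pick)
      extra <- if (length(pool2) <= short) pool2 else sample(pool2, short)
      pick <- c(pick, extra)
      tier <- c(tier, rep("0.6", length(extra)))
    }
    n_missing <- k - length(pick)
    data.frame(
      control_index = ci,
      member_id = c(control_leads[ci], v$id[pick],
                    rep(NA_character_, n_missing)),
      matched_at = c("lead", tier, rep(NA_character_, n_missing)),
      stringsAsFactors = FALSE)
  }))
  members <- if (length(rows)) do.call(rbind, rows) else
    data.frame(control_index = integer(), member_id = character(),
               matched_at = character(), stringsAsFactors = FALSE)
  new("ControlSuite", regionId = region_id, regionSize = as.integer(k + 1L),
      members = members, nRequested = as.integer(n_requested),
      seed = as.integer(seed))
}

#' Build a full control suite for one trait region
#'
#' Convenience wrapper: selects matched control leads against the pool,
#' then assembles their LD partner sets.
#'
#' @param region One region's `data.frame` (an element of [regionList()]).
#' @param pool [annotatePool()] output for the panel.
#' @param panel A [HaplotypePanel-class].
#' @param n_controls Controls requested (5000 in the full-scale design).
#' @param seed Integer seed.
#' @param window_bp Clump/partner window.
#' @param cache Optional [ldCache()].
#' @param extra_exclude Additional variant ids barred from serving as
#'   control leads (e.g. the members of every trait region, when the
#'   variant pool is small relative to the trait set).
#' @param ... Passed to [selectControlLeads()].
#' @return A [ControlSuite-class].
#' @export
buildControlSuite <- function(region, pool, panel, n_controls, seed,
                              window_bp = 250000L, cache = NULL,
                              extra_exclude = character(), ...) {
  lead_id <- region$member_id[region$is_lead]
  lead_ann <- pool[pool$variant_id == lead_id, , drop = FALSE]
  if (nrow(lead_ann) != 1L)
    stop("trait lead ", lead_id, " not in annotated pool")
  seeds <- .childSeeds(seed, 2L)
  leads <- selectControlLeads(lead_ann, pool, n = n_controls,
                              seed = seeds[1L],
                              exclude_ids = c(region$member_id,
                                              extra_exclude),
                              exclude_window_bp = window_bp, ...)
  assembleControlRegions(lead_id, leads, k = nrow(region) - 1L,
                         panel = panel, seed = seeds[2L],
                         window_bp = window_bp, cache = cache,
                         n_requested = n_controls)
}

#' Write / read a control suite as TSV
#'
#' @param suite A [ControlSuite-class].
#' @param path TSV path.
#' @export
writeControlSuite <- function(suite, path) {
  m <- suite@members
  m$region_id <- suite@regionId
  .writeTsv(m[, c("region_id", "control_index", "member_id", "matched_at")],
            path)
}
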