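## Self-contained validation experiments: statistical calibration of the
## empirical framework on null regions, and recovery of planted
## differentiation / conservation signals. Both simulate their own inputs
## and run the ordinary matching + evaluation machinery, so they exercise
## the same code paths as a real analysis.

## shared setup: panel pair, LD cache, gene set, annotated pool, and the
## measure tracks (computed FST plus standard-normal ingested-style tracks)
.experimentWorld <- function(seed, n_variants, n_chroms, n_diploids,
                             block_mean, n_genes) {
  seeds <- .childSeeds(seed, 4L)
  cfg <- simConfig(seed = seeds[1L], n_variants = n_variants,
                   n_chroms = n_chroms, n_diploids = n_diploids,
                   block_mean = block_mean)
  sim <- simulatePanels(cfg)
  target <- sim$panels[[1L]]
  cache <- ldCache(target)
  genes <- simulateGenes(sim$variants, n_genes, seeds[2L])
  pool <- suppressMessages(annotatePool(target, genes, cache = cache))
  v <- sim$variants
  tracks <- list(
    fst = fstTrack(target, sim$panels[[2L]]),
    phylop = ScoreTrack("phylop", v$chrom, v$pos,
                        .withSeed(seeds[3L], stats::rnorm(nrow(v))),
                        tail = "two_sided", provenance = "ingested"),
    gerp = ScoreTrack("gerp", v$chrom, v$pos,
                      .withSeed(seeds[4L], stats::rnorm(nrow(v))),
                      tail = "upper", provenance = "ingested"))
  list(sim = sim, target = target, cache = cache, pool = pool,
       tracks = tracks)
}

## Lead loci for the experiments: common (folded frequency >= 0.10, as GWAS
## leads are), well separated, and evaluable — enough matched pool
## candidates that the empirical p will rest on >= min_controls control
## regions rather than abstaining. Recovery is assessed where the method
## reports, not where it abstains.
.pickEvaluableLeads <- function(world, n, seed, min_candidates = 150L,
                                min_maf = 0.10, min_sep_bp = 40000L) {
  pool <- world$pool
  v <- variantInfo(world$target)
  eligible <- which(v$id %in% pool$variant_id[pool$maf >= min_maf])
  .withSeed(seed, {
    chosen <- integer(0)
    for (i in sample(eligible)) {
      sep_ok <- all(v$chrom[chosen] != v$chrom[i] |
                    abs(v$pos[chosen] - v$pos[i]) >= min_sep_bp)
      if (!sep_ok) next
      la <- pool[pool$variant_id == v$id[i], ]
      n_cand <- sum((pool$chrom != la$chrom |
                     abs(pool$pos - la$pos) > 250000L) &
                    abs(pool$maf - la$maf) <= 0.05 &
                    .inRelWindow(pool$n_ld_buddies, la$n_ld_buddies, 0.10) &
                    .inRelWindow(pool$gene_density, la$gene_density, 5.0) &
                    .inRelWindow(pool$gene_distance, la$gene_distance, 5.0),
                    na.rm = TRUE)
      if (n_cand < min_candidates) next
      chosen <- c(chosen, i)
      if (length(chosen) == n) break
    }
    if (length(chosen) < n)
      stop("could not place ", n, " evaluable leads")
    sort(chosen)
  })
}

## evaluate a set of regions against freshly built matched control suites
.evaluateRegions <- function(world, regions, n_controls, seed,
                             min_controls = 100L,
                             registry = defaultMeasureRegistry()) {
  rl <- regionList(regions)
  seeds <- .childSeeds(seed, length(rl))
  ## at desk scale the trait set is a visible fraction of the pool, so no
  ## trait-region member may serve as a control lead for any region
  trait_members <- unique(regions$member_id)
  rows <- list()
  for (i in seq_along(rl)) {
    region <- rl[[i]]
    suite <- suppressMessages(buildControlSuite(
      region, world$pool, world$target, n_controls, seeds[i],
      cache = world$cache, extra_exclude = trait_members))
    for (ms in names(world$tracks)) {
      reg <- registry[registry$measure == ms, ]
      track <- world$tracks[[ms]]
      obs <- regionMedian(
        .applyTransform(lookupTrackValues(track, region), reg$transform))
      null <- buildNull(suite, track, world$target,
                        transform = reg$transform)
      p <- NA_real_; z <- NA_real_
      if (!null@removed && !is.na(obs)) {
        p <- suppressMessages(empiricalP(obs, null, tail = reg$tail,
                                         min_controls = min_controls))
        z <- suppressMessages(zScore(obs, null))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = names(rl)[i], measure = ms, observed_median = obs,
        n_used = null@nUsed, p = p, z = z, removed = null@removed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Null calibration of the matched-control empirical p
#'
#' Simulates a multi-population world, draws `n_regions` random trait-like
#' regions from the same generator as their controls, evaluates each
#' against `n_controls` matched control regions per measure (computed FST
#' between the two populations, plus standard-normal two-sided and upper
#' ingested-style tracks), and reports the fraction of valid empirical
#' p-values below `alpha` per measure. Under the null this fraction should
#' be close to `alpha`.
#'
#' @param seed Integer seed.
#' @param n_regions Null regions to evaluate (default 200).
#' @param n_controls Matched controls requested per region (default 500;
#'   the attainable number varies by region, as with real data).
#' @param alpha Nominal level (default 0.05).
#' @param n_variants,n_chroms,n_diploids,block_mean,n_genes World size.
#' @return List with `fractions` (named per-measure fraction of valid p
#'   below `alpha`), `n_valid` (valid p count per measure), and `results`
#'   (the full per-region table).
#' @export
nullCalibration <- function(seed, n_regions = 200L, n_controls = 500L,
                            alpha = 0.05, n_variants = 24000L,
                            n_chroms = 24L, n_diploids = 60L,
                            block_mean = 12, n_genes = 1600L) {
  seeds <- .childSeeds(seed, 3L)
  world <- .experimentWorld(seeds[1L], n_variants, n_chroms, n_diploids,
                            block_mean, n_genes)
  leads <- .pickEvaluableLeads(world, n_regions, seeds[2L])
  regions <- regionsFromLeads(world$target, leads, cache = world$cache)
  res <- .evaluateRegions(world, regions, n_controls, seeds[3L])
  fr <- tapply(res$p, res$measure, function(p) mean(p < alpha, na.rm = TRUE))
  nv <- tapply(res$p, res$measure, function(p) sum(!is.na(p)))
  list(fractions = fr[names(world$tracks)],
       n_valid = nv[names(world$tracks)], results = res)
}

#' Recovery of planted differentiation and conservation signals
#'
#' Simulates a world with `n_regions` trait regions of which `n_diff`
#' receive a planted allele-frequency shift of `delta` in the second
#' population (elevating FST) and `n_cons` receive a `shift`-sd shift of
#' the two-sided conservation-style track over their members; the rest are
#' null. Each region is then evaluated against its own matched controls. A
#' planted region counts as recovered when it attains `|z| >=` `z_threshold`
#' with the planted sign and empirical p < `alpha` on its measure; a null
#' region counts as flagged per measure under the same rule.
#'
#' @inheritParams nullCalibration
#' @param n_regions Total regions (default 50).
#' @param n_diff,n_cons Planted differentiated / conserved-track regions.
#' @param delta Planted frequency shift (default 0.6).
#' @param shift Planted track shift in track sd units (default 3).
#' @param z_threshold Extreme-signature threshold (default 1.5).
#' @return List with `recovered_diff`, `recovered_cons` (counts),
#'   `null_flagged` (per-measure counts over null regions), `n_null`,
#'   and `results` (per-region table with a `planted` column).
#' @export
plantedRecovery <- function(seed, n_regions = 50L, n_diff = 10L,
                            n_cons = 10L, delta = 0.6, shift = 3,
                            alpha = 0.05, z_threshold = 1.5,
                            n_controls = 500L, n_variants = 24000L,
                            n_chroms = 24L, n_diploids = 60L,
                            block_mean = 12, n_genes = 1600L) {
  seeds <- .childSeeds(seed, 5L)
  world <- .experimentWorld(seeds[1L], n_variants, n_chroms, n_diploids,
                            block_mean, n_genes)
  leads <- .pickEvaluableLeads(world, n_regions, seeds[2L])
  regions <- regionsFromLeads(world$target, leads, cache = world$cache)
  rl <- regionList(regions)

  planted <- .withSeed(seeds[3L], {
    lab <- rep("null", n_regions)
    at <- sample.int(n_regions, n_diff + n_cons)
    lab[at[seq_len(n_diff)]] <- "differentiated"
    lab[at[n_diff + seq_len(n_cons)]] <- "conserved"
    lab
  })
  names(planted) <- names(rl)

  ## plant: frequency shifts in the comparison population (FST up);
  ## track shifts on the two-sided conservation-style track
  sig_seeds <- .childSeeds(seeds[4L], n_regions)
  sim <- world$sim
  for (i in which(planted == "differentiated"))
    sim <- plantSignal(sim, list(type = "differentiated",
                                 pop = names(sim$panels)[[2L]],
                                 loci = rl[[i]]$member_id, delta = delta),
                       sig_seeds[i])
  world$tracks$fst <- fstTrack(world$target, sim$panels[[2L]])
  for (i in which(planted == "conserved"))
    world$tracks$phylop <- plantTrackShift(
      world$tracks$phylop, rl[[i]]$chrom, rl[[i]]$pos, shift)

  res <- .evaluateRegions(world, regions, n_controls, seeds[5L])
  res$planted <- planted[res$region_id]

  hit <- function(df) !is.na(df$p) & !is.na(df$z) &
    df$p < alpha & df$z >= z_threshold
  diff_rows <- res[res$measure == "fst" & res$planted == "differentiated", ]
  cons_rows <- res[res$measure == "phylop" & res$planted == "conserved", ]
  null_rows <- res[res$planted == "null", ]
  null_flagged <- tapply(
    !is.na(null_rows$p) & !is.na(null_rows$z) & null_rows$p < alpha &
      abs(null_rows$z) >= z_threshold,
    null_rows$measure, sum)
  list(recovered_diff = sum(hit(diff_rows)),
       recovered_cons = sum(hit(cons_rows)),
       null_flagged = null_flagged,
       n_null = sum(planted == "null"), results = res)
}
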