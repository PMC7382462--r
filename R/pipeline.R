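## End-to-end orchestration: clump -> annotate/match -> measures ->
## evaluate -> cluster -> enrich, with reproducible seeding and
## self-describing TSV outputs plus run metadata.

#' Pipeline run configuration
#'
#' Defaults mirror the full-scale design (5000 controls, alpha 0.05,
#' |z| threshold 1.5, dendrogram cut height 7, 5000 random regions x 1000
#' iterations); fixture-scale runs override them downward.
#'
#' @param vcf,sample_map,gwas,genes Input paths (see the readers).
#' @param tracks Named character vector: ingested measure name -> track
#'   path.
#' @param target_pop Population used for LD, matching and single-panel
#'   measures.
#' @param comparison_pop Second population for FST (and XP-EHH if
#'   requested); `NULL` disables cross-population measures.
#' @param ancestral Optional path to an ancestral-allele TSV
#'   (`variant_id`, `ancestral_allele` in 0/1) enabling iHS.
#' @param measures Measures to evaluate; defaults to FST, Beta and every
#'   ingested track. Add `"ihs"`, `"xpehh"`, `"ies"` to enable the EHH
#'   family.
#' @param registry Measure registry `data.frame` (default
#'   [defaultMeasureRegistry()]).
#' @param clump A [clumpConfig()].
#' @param n_controls Matched controls per region.
#' @param min_controls Minimum usable controls for a valid empirical p.
#' @param alpha Significance threshold on empirical p.
#' @param z_threshold Extreme-signature |z| threshold.
#' @param cut_height Dendrogram cut height.
#' @param n_random,n_iter Genome-wide pool size and iteration counts for
#'   enrichment.
#' @param matched_n_iter Iterations for the matched-null enrichment.
#' @param density_window_bp Gene-density window.
#' @param seed Master seed; every stage draws from child seeds of it.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(vcf, sample_map, gwas, genes, tracks = character(),
                      target_pop, comparison_pop = NULL, ancestral = NULL,
                      measures = NULL, registry = defaultMeasureRegistry(),
                      clump = clumpConfig(), n_controls = 5000L,
                      min_controls = 100L, alpha = 0.05,
                      z_threshold = 1.5, cut_height = 7.0,
                      n_random = 5000L, n_iter = 1000L,
                      matched_n_iter = 1000L, density_window_bp = 100000L,
                      seed) {
  stopifnot(!missing(seed), alpha > 0, alpha <= 1, z_threshold >= 0)
  if (is.null(measures))
    measures <- c("fst"[!is.null(comparison_pop)], "beta", names(tracks))
  structure(list(vcf = vcf, sample_map = sample_map, gwas = gwas,
                 genes = genes, tracks = tracks, target_pop = target_pop,
                 comparison_pop = comparison_pop, ancestral = ancestral,
                 measures = measures, registry = registry, clump = clump,
                 n_controls = as.integer(n_controls),
                 min_controls = as.integer(min_controls), alpha = alpha,
                 z_threshold = z_threshold, cut_height = cut_height,
                 n_random = as.integer(n_random),
                 n_iter = as.integer(n_iter),
                 matched_n_iter = as.integer(matched_n_iter),
                 density_window_bp = as.integer(density_window_bp),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a RunConfig from YAML
#'
#' Scalar fields map directly onto [runConfig()] arguments; `clump` may be
#' a nested mapping of [clumpConfig()] arguments.
#'
#' @param path YAML file.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$clump)) y$clump <- do.call(clumpConfig, y$clump)
  if (!is.null(y$tracks)) y$tracks <- unlist(y$tracks)
  if (!is.null(y$registry) && is.character(y$registry))
    y$registry <- readMeasureRegistry(y$registry)
  do.call(runConfig, y)
}

## compute the requested per-variant measure tracks from panels
.computeTracks <- function(cfg, panels, ancestral) {
  target <- panels[[cfg$target_pop]]
  tracks <- list()
  v <- variantInfo(target)
  if ("fst" %in% cfg$measures) {
    if (is.null(cfg$comparison_pop))
      stop("fst requires a comparison population")
    tracks$fst <- fstTrack(target, panels[[cfg$comparison_pop]])
  }
  if ("beta" %in% cfg$measures) tracks$beta <- betaTrack(target)
  if ("ihs" %in% cfg$measures) {
    if (is.null(ancestral)) stop("ihs requires an ancestral-allele map")
    sc <- ihsScores(target, ancestral)
    ok <- !is.na(sc$ihs)
    mi <- match(sc$variant_id[ok], v$id)
    tracks$ihs <- ScoreTrack("ihs", v$chrom[mi], v$pos[mi], sc$ihs[ok],
                             tail = "upper", provenance = "computed")
  }
  if ("xpehh" %in% cfg$measures) {
    sc <- xpehhScores(target, panels[[cfg$comparison_pop]])
    ok <- !is.na(sc$xpehh)
    mi <- match(sc$variant_id[ok], v$id)
    tracks$xpehh <- ScoreTrack("xpehh", v$chrom[mi], v$pos[mi],
                               sc$xpehh[ok], tail = "upper",
                               provenance = "computed")
  }
  if ("ies" %in% cfg$measures) {
    sc <- iesScores(target)
    mi <- match(sc$variant_id, v$id)
    tracks$ies <- ScoreTrack("ies", v$chrom[mi], v$pos[mi], sc$ies,
                             tail = "upper", provenance = "computed")
  }
  for (nm in names(cfg$tracks))
    if (nm %in% cfg$measures)
      tracks[[nm]] <- readScoreTrack(
        cfg$tracks[[nm]], nm,
        tail = cfg$registry$tail[match(nm, cfg$registry$measure)])
  tracks
}

## p-value matrix (regions x measures) for one random region set evaluated
## against its own matched controls
.randomSetPValues <- function(seed, n_regions, pool, panel, cache, tracks,
                              registry, cfg) {
  lead_ids <- .withSeed(seed, sample(pool$variant_id, n_regions))
  leads <- match(lead_ids, variantInfo(panel)$id)
  regions <- regionsFromLeads(panel, leads, r2 = cfg$clump$r2_region,
                              window_bp = cfg$clump$window_bp,
                              cache = cache)
  rl <- regionList(regions)
  suite_seeds <- .childSeeds(seed, length(rl))
  out <- matrix(NA_real_, length(rl), length(tracks),
                dimnames = list(names(rl), names(tracks)))
  for (ri in seq_along(rl)) {
    suite <- buildControlSuite(rl[[ri]], pool, panel, cfg$n_controls,
                               suite_seeds[ri],
                               window_bp = cfg$clump$window_bp,
                               cache = cache)
    for (ms in names(tracks)) {
      reg <- registry[registry$measure == ms, ]
      vals <- .applyTransform(lookupTrackValues(tracks[[ms]], rl[[ri]]),
                              reg$transform)
      obs <- regionMedian(vals)
      null <- buildNull(suite, tracks[[ms]], panel,
                        transform = reg$transform)
      if (!null@removed && !is.na(obs))
        out[ri, ms] <- suppressMessages(
          empiricalP(obs, null, tail = reg$tail,
                     min_controls = cfg$min_controls))
    }
  }
  out
}

#' Run the full pipeline
#'
#' Stages execute in order: clump -> annotate/match -> measures ->
#' evaluate -> cluster -> enrich. Every output TSV is written to `outdir`
#' together with `run_metadata.json` (seed and parameters); a rerun with
#' the same configuration is byte-identical.
#'
#' @param cfg A [runConfig()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`regions`,
#'   `pool`, `suites`, `tracks`, `results`, `zmatrix`, `clusters`,
#'   `extreme`, `enrichment_genomewide`, `enrichment_matched`).
#' @export
runPipeline <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .childSeeds(cfg$seed, 6L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- inputs -------------------------------------------------------------
  panels <- stage("input", {
    sm <- readSampleMap(cfg$sample_map)
    pops <- unique(c(cfg$target_pop, cfg$comparison_pop))
    stats::setNames(
      lapply(pops, function(p) readHaplotypePanel(cfg$vcf, sm, p)), pops)
  })
  target <- panels[[cfg$target_pop]]
  gwas <- stage("input", readGwas(cfg$gwas))
  genes <- stage("input", readGeneBed(cfg$genes))
  ancestral <- NULL
  if (!is.null(cfg$ancestral)) {
    aa <- .readTsv(cfg$ancestral)
    ancestral <- stats::setNames(as.integer(aa$ancestral_allele),
                                 aa$variant_id)
  }

  ## --- clump --------------------------------------------------------------
  regions <- stage("clump", clumpRegions(gwas, target, cfg$clump))
  if (nrow(regions) == 0L) stop("stage 'clump': no regions found")
  .writeTsv(regions, file.path(outdir, "regions.tsv"))

  ## --- annotate / match ---------------------------------------------------
  cache <- ldCache(target)
  pool <- stage("annotate", annotatePool(
    target, genes, density_window_bp = cfg$density_window_bp,
    buddy_window_bp = cfg$clump$window_bp, cache = cache))
  .writeTsv(pool, file.path(outdir, "pool_annotations.tsv"))

  rl <- regionList(regions)
  in_pool <- vapply(rl, function(r)
    r$member_id[r$is_lead] %in% pool$variant_id, logical(1L))
  if (any(!in_pool)) {
    message("runPipeline: dropped ", sum(!in_pool),
            " region(s) whose lead is not annotatable")
    regions <- regions[regions$region_id %in% names(rl)[in_pool], ]
    rl <- rl[in_pool]
  }
  suite_seeds <- .childSeeds(seeds[1L], length(rl))
  suites <- stage("match", {
    s <- lapply(seq_along(rl), function(i)
      buildControlSuite(rl[[i]], pool, target, cfg$n_controls,
                        suite_seeds[i], window_bp = cfg$clump$window_bp,
                        cache = cache))
    stats::setNames(s, names(rl))
  })
  all_members <- do.call(rbind, lapply(names(suites), function(rid) {
    m <- suites[[rid]]@members
    if (nrow(m) == 0L) return(NULL)
    cbind(region_id = rid, m)
  }))
  .writeTsv(all_members, file.path(outdir, "control_suites.tsv"))

  ## --- measures -----------------------------------------------------------
  tracks <- stage("measure", .computeTracks(cfg, panels, ancestral))
  for (nm in names(tracks))
    if (tracks[[nm]]@provenance == "computed")
      writeScoreTrack(tracks[[nm]],
                      file.path(outdir, paste0("track_", nm, ".tsv")))

  ## --- evaluate -----------------------------------------------------------
  results <- stage("evaluate", evaluateAll(
    regions, suites, tracks, cfg$registry, target,
    min_controls = cfg$min_controls))
  .writeTsv(results, file.path(outdir, "results.tsv"))

  ## --- cluster ------------------------------------------------------------
  zm <- stage("cluster", buildZMatrix(results))
  clusters <- stage("cluster", clusterRegions(zm, cfg$cut_height))
  extreme <- extremeRegions(zm, cfg$z_threshold)
  .writeTsv(data.frame(region_id = rownames(zValues(zm)), zValues(zm),
                       check.names = FALSE),
            file.path(outdir, "zmatrix.tsv"))
  .writeTsv(data.frame(region_id = names(clusters),
                       cluster = unname(clusters)),
            file.path(outdir, "clusters.tsv"))
  .writeTsv(data.frame(region_id = extreme),
            file.path(outdir, "extreme_regions.tsv"))

  ## --- enrich -------------------------------------------------------------
  gw <- stage("enrich", {
    pool_lead_seed <- seeds[2L]
    pool_leads <- .withSeed(pool_lead_seed,
      sample(pool$variant_id, cfg$n_random, replace = TRUE))
    rand_regions <- regionsFromLeads(
      target, match(unique(pool_leads), variantInfo(target)$id),
      r2 = cfg$clump$r2_region, window_bp = cfg$clump$window_bp,
      cache = cache)
    rand_rl <- regionList(rand_regions)
    rand_rl <- rand_rl[match(pool_leads, names(rand_rl))]
    rows <- lapply(names(tracks), function(ms) {
      reg <- cfg$registry[cfg$registry$measure == ms, ]
      pool_med <- vapply(rand_rl, function(r)
        regionMedian(.applyTransform(lookupTrackValues(tracks[[ms]], r),
                                     reg$transform)), numeric(1L))
      trait_med <- results$observed_median[results$measure == ms]
      cbind(measure = ms,
            genomewideEnrichment(trait_med, pool_med,
                                 n_random = cfg$n_random,
                                 n_iter = cfg$n_iter, seed = seeds[3L]))
    })
    do.call(rbind, rows)
  })
  .writeTsv(gw, file.path(outdir, "enrichment_genomewide.tsv"))

  me <- stage("enrich", {
    iter_cache <- new.env(parent = emptyenv())
    gen_for <- function(ms) function(s) {
      key <- as.character(s)
      if (is.null(iter_cache[[key]]))
        iter_cache[[key]] <- .randomSetPValues(
          s, length(rl), pool, target, cache, tracks, cfg$registry, cfg)
      iter_cache[[key]][, ms]
    }
    rows <- lapply(names(tracks), function(ms) {
      trait_p <- results$p[results$measure == ms]
      cbind(measure = ms,
            matchedEnrichment(trait_p, gen_for(ms),
                              n_iter = cfg$matched_n_iter,
                              alpha = cfg$alpha, seed = seeds[4L]))
    })
    do.call(rbind, rows)
  })
  .writeTsv(me, file.path(outdir, "enrichment_matched.tsv"))

  params <- unclass(cfg[!names(cfg) %in% "registry"])
  params$clump <- unclass(params$clump)
  meta <- list(seed = cfg$seed,
               package_version = as.character(utils::packageVersion("evoreg")),
               parameters = params)
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(regions = regions, pool = pool, suites = suites,
                 tracks = tracks, results = results, zmatrix = zm,
                 clusters = clusters, extreme = extreme,
                 enrichment_genomewide = gw, enrichment_matched = me))
}
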