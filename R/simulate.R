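## Founder-mosaic haplotype simulator and fixture-bundle writer. Haplotypes
## are mosaic copies of a small founder set with per-bp recombination and
## per-entry mutation; variants come in founder-pattern blocks, which gives
## the block LD structure the matching and EHH machinery need. This is a
## testing generator, not a coalescent simulator.

#' Simulation configuration
#'
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @param n_pops Number of populations.
#' @param n_diploids Diploid samples per population.
#' @param n_variants Total variants, split evenly over `n_chroms`.
#' @param n_chroms Number of chromosomes.
#' @param n_founders Founder haplotypes.
#' @param block_mean Mean variants per founder-pattern block (consecutive
#'   variants sharing one founder carrier subset, i.e. one LD block).
#' @param gap_mean_bp Mean inter-variant spacing in bp.
#' @param recomb_per_bp Per-bp probability of a founder switch between
#'   adjacent variants.
#' @param mutation_rate Per-entry allele flip probability.
#' @param drift_alpha Dirichlet concentration of per-population founder
#'   weights; smaller means more drift (more background differentiation).
#' @param planted_signals List of signal descriptors (see
#'   [plantSignal()] / [writeFixtureBundle()]).
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed, n_pops = 2L, n_diploids = 60L,
                      n_variants = 2000L, n_chroms = 4L, n_founders = 8L,
                      block_mean = 6, gap_mean_bp = 1000,
                      recomb_per_bp = 5e-6, mutation_rate = 0.002,
                      drift_alpha = 8, planted_signals = list()) {
  stopifnot(!missing(seed), mutation_rate >= 0, mutation_rate <= 1,
            recomb_per_bp >= 0, recomb_per_bp <= 1, n_founders >= 2)
  structure(list(seed = as.integer(seed), n_pops = n_pops,
                 n_diploids = n_diploids, n_variants = n_variants,
                 n_chroms = n_chroms, n_founders = n_founders,
                 block_mean = block_mean, gap_mean_bp = gap_mean_bp,
                 recomb_per_bp = recomb_per_bp,
                 mutation_rate = mutation_rate, drift_alpha = drift_alpha,
                 planted_signals = planted_signals),
            class = "SimConfig")
}

.rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  g / sum(g)
}

#' Simulate multi-population haplotype panels
#'
#' Variants are laid out with exponential spacing and partitioned into
#' founder-pattern blocks; each block is assigned a founder carrier subset
#' (subset size weighted 1/k to skew folded frequencies low). Haplotypes
#' mosaic-copy founders with per-gap switch probability
#' `1 - exp(-recomb_per_bp * gap)` and per-entry mutation. Populations draw
#' founders with population-specific Dirichlet weights, yielding realistic
#' mild background differentiation. The ancestral allele is 0 at every site
#' (allele 1 is the derived state carried by the block's founder subset).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [simConfig()].
#' @return List with `panels` (named list of [HaplotypePanel-class], one
#'   per population `POP1`, `POP2`, ...), `variants` (shared variant
#'   table), `ancestral` (named 0/1 vector), `founders` (founder matrix).
#' @export
simulatePanels <- function(cfg) {
  .withSeed(cfg$seed, {
    V <- cfg$n_variants
    per_chrom <- rep(V %/% cfg$n_chroms, cfg$n_chroms)
    per_chrom[seq_len(V %% cfg$n_chroms)] <-
      per_chrom[seq_len(V %% cfg$n_chroms)] + 1L
    chrom <- rep(paste0("chr", seq_len(cfg$n_chroms)), per_chrom)
    pos <- unlist(lapply(per_chrom, function(m)
      cumsum(pmax(1L, round(stats::rexp(m, 1 / cfg$gap_mean_bp)))) + 1000L))
    variants <- data.frame(
      id = sprintf("v%05d", seq_len(V)), chrom = chrom,
      pos = as.integer(pos), ref = "A", alt = "G",
      stringsAsFactors = FALSE)

    ## founder-pattern blocks per chromosome
    F <- matrix(0L, cfg$n_founders, V)
    offset <- 0L
    for (m in per_chrom) {
      done <- 0L
      while (done < m) {
        len <- min(2L + stats::rpois(1L, max(0, cfg$block_mean - 2)),
                   m - done)
        k <- sample.int(cfg$n_founders - 1L, 1L,
                        prob = 1 / seq_len(cfg$n_founders - 1L))
        carriers <- sample.int(cfg$n_founders, k)
        F[carriers, offset + done + seq_len(len)] <- 1L
        done <- done + len
      }
      offset <- offset + m
    }

    gaps <- c(0L, diff(pos))
    gaps[c(1L, cumsum(per_chrom[-cfg$n_chroms]) + 1L)] <- NA  # chrom starts
    p_switch <- 1 - exp(-cfg$recomb_per_bp * gaps)

    panels <- list()
    for (pp in seq_len(cfg$n_pops)) {
      w <- .rdirichlet1(cfg$n_founders, cfg$drift_alpha)
      n_hap <- 2L * cfg$n_diploids
      H <- matrix(0L, n_hap, V)
      for (h in seq_len(n_hap)) {
        path <- integer(V)
        cur <- sample.int(cfg$n_founders, 1L, prob = w)
        for (j in seq_len(V)) {
          if (is.na(p_switch[j]) ||
              (p_switch[j] > 0 && stats::runif(1L) < p_switch[j]))
            cur <- sample.int(cfg$n_founders, 1L, prob = w)
          path[j] <- cur
        }
        H[h, ] <- F[cbind(path, seq_len(V))]
      }
      if (cfg$mutation_rate > 0) {
        n_flip <- stats::rbinom(1L, length(H), cfg$mutation_rate)
        if (n_flip > 0L) {
          at <- sample.int(length(H), n_flip)
          H[at] <- 1L - H[at]
        }
      }
      pop <- paste0("POP", pp)
      panels[[pop]] <- HaplotypePanel(pop, variants, H)
    }
    ## the panel constructor coordinate-sorts columns; keep the shared
    ## variant table and founder matrix in that same order
    o <- order(variants$chrom, variants$pos)
    variants <- variants[o, , drop = FALSE]
    rownames(variants) <- NULL
    F <- F[, o, drop = FALSE]
    ancestral <- stats::setNames(rep(0L, V), variants$id)
    list(panels = panels, variants = variants, ancestral = ancestral,
         founders = F)
  })
}

#' Plant an evolutionary signal into simulated panels
#'
#' Signal types:
#' \describe{
#'   \item{sweep}{`pop`, `locus` (variant id or index), `freq` (target
#'     carrier frequency), `span_bp` (copied segment width, default 1e5):
#'     copies one donor haplotype's segment around the locus into random
#'     haplotypes until the donor class reaches `freq`, elevating local
#'     haplotype homozygosity (and iHH contrast).}
#'   \item{differentiated}{`pop`, `loci`, `delta`: shifts the allele-1
#'     frequency at each locus in one population by `delta` (clipped to
#'     [0, 1]), elevating FST.}
#'   \item{balanced}{`locus`, `n_neighbors` (default 8), `span_bp`
#'     (default 1000), `jitter` (default 2): in every population, sets the
#'     core to folded frequency 0.5 and overwrites the nearest neighbors
#'     within the window with lightly jittered copies of the core column,
#'     producing the frequency-matched cluster that elevates Beta.}
#' }
#' `conserved_track` signals act on tracks; see [plantTrackShift()].
#'
#' @param sim A [simulatePanels()] result.
#' @param signal A signal descriptor list with a `type` field.
#' @param seed Integer seed.
#' @return The modified `sim`.
#' @export
plantSignal <- function(sim, signal, seed) {
  ## index on the panels' own (coordinate-sorted) variant order
  v <- variantInfo(sim$panels[[1L]])
  locIdx <- function(x) if (is.character(x)) match(x, v$id) else as.integer(x)
  .withSeed(seed, switch(signal$type,
    differentiated = {
      pop <- signal$pop
      H <- haplotypes(sim$panels[[pop]])
      for (i in locIdx(signal$loci)) {
        f <- mean(H[, i])
        ## shift in the direction with room so the between-population
        ## frequency gap realises ~delta even at high starting frequency
        target <- if (f + signal$delta <= 1) f + signal$delta else
          max(0, f - signal$delta)
        target_n <- round(target * nrow(H))
        cur_n <- sum(H[, i])
        if (target_n > cur_n) {
          at <- sample(which(H[, i] == 0L), target_n - cur_n)
          H[at, i] <- 1L
        } else if (target_n < cur_n) {
          at <- sample(which(H[, i] == 1L), cur_n - target_n)
          H[at, i] <- 0L
        }
      }
      sim$panels[[pop]] <- HaplotypePanel(pop, v, H)
      sim
    },
    sweep = {
      pop <- signal$pop
      span <- if (is.null(signal$span_bp)) 1e5 else signal$span_bp
      H <- haplotypes(sim$panels[[pop]])
      i <- locIdx(signal$locus)
      cols <- which(v$chrom == v$chrom[i] &
                    abs(v$pos - v$pos[i]) <= span / 2)
      carriers <- which(H[, i] == 1L)
      donor <- if (length(carriers)) carriers[[1L]] else 1L
      H[donor, i] <- 1L
      target_n <- round(signal$freq * nrow(H))
      others <- setdiff(seq_len(nrow(H)), donor)
      recipients <- sample(others, max(0L, target_n - 1L))
      H[recipients, cols] <- rep(H[donor, cols], each = length(recipients))
      sim$panels[[pop]] <- HaplotypePanel(pop, v, H)
      sim
    },
    balanced = {
      span <- if (is.null(signal$span_bp)) 1000 else signal$span_bp
      n_nb <- if (is.null(signal$n_neighbors)) 8L else signal$n_neighbors
      jitter <- if (is.null(signal$jitter)) 2L else signal$jitter
      i <- locIdx(signal$locus)
      nb <- which(v$chrom == v$chrom[i] & abs(v$pos - v$pos[i]) <= span / 2)
      nb <- setdiff(nb[order(abs(v$pos[nb] - v$pos[i]))], i)
      nb <- utils::head(nb, n_nb)
      for (pop in names(sim$panels)) {
        H <- haplotypes(sim$panels[[pop]])
        core <- integer(nrow(H))
        core[sample.int(nrow(H), nrow(H) %/% 2L)] <- 1L
        H[, i] <- core
        for (j in nb) {
          col <- core
          at <- sample.int(nrow(H), jitter)
          col[at] <- 1L - col[at]
          H[, j] <- col
        }
        sim$panels[[pop]] <- HaplotypePanel(pop, v, H)
      }
      sim
    },
    stop("unknown or panel-incompatible signal type: ", signal$type)))
}

#' Shift track values over a set of positions
#'
#' The track-level planted signal: adds `offset` to the track value at the
#' given positions (used to emulate a conservation shift on an ingested
#' measure).
#'
#' @param track A [ScoreTrack-class].
#' @param chrom,pos Positions to shift.
#' @param offset Additive shift.
#' @return The modified [ScoreTrack-class].
#' @export
plantTrackShift <- function(track, chrom, pos, offset) {
  at <- match(.key(chrom, pos), track@keys)
  at <- at[!is.na(at)]
  track@value[at] <- track@value[at] + offset
  track
}

#' Pick well-separated region lead loci
#'
#' Random polymorphic loci with folded frequency >= `min_maf` in the target
#' panel and pairwise distance >= `min_sep_bp` (greedy rejection).
#'
#' @param panel Target [HaplotypePanel-class].
#' @param n Number of leads.
#' @param seed Integer seed.
#' @param min_maf Minimum folded frequency.
#' @param min_sep_bp Minimum pairwise separation.
#' @return Integer vector of variant column indices.
#' @export
pickRegionLeads <- function(panel, n, seed, min_maf = 0.05,
                            min_sep_bp = 60000L) {
  v <- variantInfo(panel)
  p <- colMeans(haplotypes(panel))
  eligible <- which(pmin(p, 1 - p) >= min_maf)
  .withSeed(seed, {
    chosen <- integer(0)
    for (i in sample(eligible)) {
      ok <- all(v$chrom[chosen] != v$chrom[i] |
                abs(v$pos[chosen] - v$pos[i]) >= min_sep_bp)
      if (ok) chosen <- c(chosen, i)
      if (length(chosen) == n) break
    }
    if (length(chosen) < n)
      stop("could not place ", n, " leads at separation ", min_sep_bp)
    sort(chosen)
  })
}

#' Define trait regions from lead loci by panel LD
#'
#' Builds the region table (lead + partners at `r^2 > r2` within
#' `window_bp`) directly from panel LD, assigning each member the GWAS-side
#' fields it will carry.
#'
#' @param panel Target [HaplotypePanel-class].
#' @param leads Lead variant column indices.
#' @param r2,window_bp Membership LD threshold and window.
#' @param max_members Cap on partners per region.
#' @param cache Optional [ldCache()].
#' @return Region `data.frame` in [clumpRegions()] schema (p left `NA`).
#' @export
regionsFromLeads <- function(panel, leads, r2 = 0.9, window_bp = 250000L,
                             max_members = 20L, cache = NULL) {
  if (is.null(cache)) cache <- ldCache(panel)
  v <- variantInfo(panel)
  rows <- lapply(leads, function(i) {
    pr <- .ldPartners(cache, i, window_bp, r2)
    o <- order(-pr$r2)
    keep <- utils::head(o, max_members)
    data.frame(region_id = v$id[i],
               member_id = c(v$id[i], v$id[pr$idx[keep]]),
               chrom = v$chrom[c(i, pr$idx[keep])],
               pos = v$pos[c(i, pr$idx[keep])],
               p = NA_real_,
               r2_to_lead = c(1.0, pr$r2[keep]),
               is_lead = c(TRUE, rep(FALSE, length(keep))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate random gene intervals
#'
#' @param variants Variant table (defines chromosome extents).
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @return A `GRanges` of gene intervals.
#' @export
simulateGenes <- function(variants, n_genes, seed) {
  .withSeed(seed, {
    chroms <- unique(variants$chrom)
    ends <- vapply(chroms, function(ch)
      max(variants$pos[variants$chrom == ch]), integer(1L))
    ch <- sample(chroms, n_genes, replace = TRUE)
    len <- round(stats::runif(n_genes, 5000, 50000))
    start <- vapply(seq_len(n_genes), function(i)
      round(stats::runif(1L, 1, max(2, ends[[ch[i]]] - len[i]))),
      numeric(1L))
    GenomicRanges::GRanges(ch, IRanges::IRanges(start, start + len - 1L))
  })
}

#' Write a complete fixture bundle
#'
#' Simulates panels, applies planted signals, derives trait regions and
#' GWAS p-values that clump back into exactly those regions, simulates gene
#' intervals, ingested-style score tracks (standard normal, with any
#' `conserved_track` signals applied over their target regions), a dated
#' species tree and per-site tip states, and writes everything in the
#' formats the readers accept, plus a `truth.json` listing the planted
#' structure.
#'
#' Signal descriptors in `cfg$planted_signals` reference regions by index
#' (`region = i`); `sweep`/`balanced`/`differentiated` act on the panels at
#' region i's lead (differentiated on all of region i's members), and
#' `conserved_track` (`track`, `offset`) shifts that track over region i's
#' member positions.
#'
#' @param cfg A [simConfig()].
#' @param dir Output directory (created if needed).
#' @param n_regions Number of trait regions to derive.
#' @param n_genes Simulated gene count.
#' @param track_measures Named character vector: ingested track name ->
#'   tail convention.
#' @param n_parsimony_sites Tip-state sites to simulate.
#' @return Invisibly, the truth list (also written as `truth.json`).
#' @export
writeFixtureBundle <- function(cfg, dir, n_regions = 12L, n_genes = 60L,
                               track_measures = c(phylop = "two_sided",
                                                  gerp = "upper"),
                               n_parsimony_sites = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .childSeeds(cfg$seed, 10L)
  sim <- simulatePanels(cfg)
  target <- names(sim$panels)[[1L]]

  leads <- pickRegionLeads(sim$panels[[target]], n_regions, seeds[1L])

  ## panel-level signals first (they alter LD), then region membership,
  ## then frequency shifts (pop-2 only, target-panel LD unaffected)
  sig_seeds <- .childSeeds(seeds[2L], max(1L, length(cfg$planted_signals)))
  signals <- cfg$planted_signals
  for (si in seq_along(signals)) {
    sg <- signals[[si]]
    if (sg$type %in% c("sweep", "balanced")) {
      sg$locus <- leads[sg$region]
      sim <- plantSignal(sim, sg, sig_seeds[si])
    }
  }
  cache <- ldCache(sim$panels[[target]])
  regions <- regionsFromLeads(sim$panels[[target]], leads, cache = cache)
  rl <- regionList(regions)
  lead_ids <- variantInfo(sim$panels[[target]])$id[leads]
  for (si in seq_along(signals)) {
    sg <- signals[[si]]
    if (sg$type == "differentiated") {
      sg$loci <- rl[[lead_ids[sg$region]]]$member_id
      sim <- plantSignal(sim, sg, sig_seeds[si])
    }
  }

  ## GWAS p-values: leads lowest, members <= 1e-4, background > 0.1
  v <- sim$variants
  gwas <- .withSeed(seeds[3L], {
    p <- stats::runif(nrow(v), 0.1, 1)
    for (rid in names(rl)) {
      r <- rl[[rid]]
      mi <- match(r$member_id, v$id)
      p[mi] <- 10^-stats::runif(length(mi), 4.05, 5)
      p[mi[r$is_lead]] <- 10^-stats::runif(1L, 5, 8)
    }
    data.frame(variant_id = v$id, chrom = v$chrom, pos = v$pos, p = p,
               stringsAsFactors = FALSE)
  })

  genes <- simulateGenes(v, n_genes, seeds[4L])

  tracks <- list()
  tseeds <- .childSeeds(seeds[5L], length(track_measures))
  for (ti in seq_along(track_measures)) {
    nm <- names(track_measures)[ti]
    vals <- .withSeed(tseeds[ti], stats::rnorm(nrow(v)))
    tr <- ScoreTrack(nm, v$chrom, v$pos, vals,
                     tail = track_measures[[ti]], provenance = "ingested")
    tracks[[nm]] <- tr
  }
  for (si in seq_along(signals)) {
    sg <- signals[[si]]
    if (sg$type == "conserved_track") {
      r <- rl[[lead_ids[sg$region]]]
      tracks[[sg$track]] <-
        plantTrackShift(tracks[[sg$track]], r$chrom, r$pos, sg$offset)
    }
  }

  ## dated species tree + tip states
  tree <- .withSeed(seeds[6L], {
    tr <- ape::rcoal(8L, tip.label = c("human", paste0("sp", 1:7)))
    tr$edge.length <- tr$edge.length * (100 / max(
      ape::node.depth.edgelength(tr)))
    tr
  })
  tip_states <- .withSeed(seeds[7L], {
    m <- matrix(sample(c("A", "C", "G", "T"), n_parsimony_sites * 8L,
                       replace = TRUE), n_parsimony_sites, 8L,
                dimnames = list(sprintf("site%03d", 1:n_parsimony_sites),
                                tree$tip.label))
    gapped <- sample.int(n_parsimony_sites, n_parsimony_sites %/% 5L)
    for (g in gapped)
      m[g, sample.int(8L, sample(1:3, 1L))] <- "-"
    m
  })

  ## write everything
  sm <- writePanelVcf(unname(sim$panels), file.path(dir, "panel.vcf"))
  .writeTsv(sm, file.path(dir, "sample_map.tsv"))
  .writeTsv(gwas, file.path(dir, "gwas.tsv"))
  rtracklayer::export(genes, file.path(dir, "genes.bed"), format = "bed")
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  for (nm in names(tracks))
    writeScoreTrack(tracks[[nm]], file.path(dir, "tracks",
                                            paste0(nm, ".tsv")))
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  .writeTsv(data.frame(site_id = rownames(tip_states), tip_states,
                       stringsAsFactors = FALSE),
            file.path(dir, "tip_states.tsv"))
  writeMeasureRegistry(defaultMeasureRegistry(),
                       file.path(dir, "registry.yaml"))
  .writeTsv(regions, file.path(dir, "regions_truth.tsv"))
  aa <- sim$ancestral
  .writeTsv(data.frame(variant_id = names(aa), ancestral_allele = aa),
            file.path(dir, "ancestral.tsv"))

  truth <- list(
    seed = cfg$seed, target_population = target,
    n_regions = length(rl),
    regions = lapply(names(rl), function(rid)
      list(region_id = rid, members = rl[[rid]]$member_id)),
    planted_signals = lapply(seq_along(signals), function(si) {
      sg <- signals[[si]]
      c(list(region_id = lead_ids[sg$region]), sg)
    }),
    track_measures = as.list(track_measures))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
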