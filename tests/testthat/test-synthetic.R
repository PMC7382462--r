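test_that("simulation is deterministic and founder-faithful", {
  cfg <- simConfig(seed = 13, n_variants = 300, n_chroms = 2,
                   n_diploids = 20)
  a <- simulatePanels(cfg)
  b <- simulatePanels(cfg)
  expect_identical(haplotypes(a$panels$POP1), haplotypes(b$panels$POP1))
  expect_identical(haplotypes(a$panels$POP2), haplotypes(b$panels$POP2))

  ## no recombination, no mutation: every haplotype IS a founder row
  cfg0 <- simConfig(seed = 13, n_variants = 200, n_chroms = 1,
                    n_diploids = 15, recomb_per_bp = 0, mutation_rate = 0)
  s0 <- simulatePanels(cfg0)
  H <- haplotypes(s0$panels$POP1)
  fkey <- apply(s0$founders, 1, paste, collapse = "")
  hkey <- apply(H, 1, paste, collapse = "")
  expect_true(all(hkey %in% fkey))
})

test_that("two founders without recombination give perfect LD", {
  cfg <- simConfig(seed = 29, n_variants = 150, n_chroms = 1,
                   n_diploids = 20, n_founders = 2, recomb_per_bp = 0,
                   mutation_rate = 0)
  sim <- simulatePanels(cfg)
  panel <- sim$panels$POP1
  f <- colMeans(haplotypes(panel))
  poly <- which(f > 0 & f < 1)
  expect_gt(length(poly), 2)
  pairs <- utils::combn(poly[1:min(8, length(poly))], 2)
  for (j in seq_len(ncol(pairs)))
    expect_equal(rSquared(panel, pairs[1, j], pairs[2, j]), 1.0)
})

test_that("differentiated planting opens the stated frequency gap", {
  cfg <- simConfig(seed = 31, n_variants = 300, n_chroms = 1,
                   n_diploids = 30)
  sim <- simulatePanels(cfg)
  f2 <- colMeans(haplotypes(sim$panels$POP2))
  locus <- which(abs(f2 - 0.2) == min(abs(f2 - 0.2)))[1]
  before <- f2[locus]
  sim2 <- plantSignal(sim, list(type = "differentiated", pop = "POP2",
                                loci = locus, delta = 0.6), seed = 1)
  after <- colMeans(haplotypes(sim2$panels$POP2))[locus]
  expect_equal(after, before + 0.6, tolerance = 0.02)
  ## the target panel is untouched
  expect_identical(haplotypes(sim2$panels$POP1),
                   haplotypes(sim$panels$POP1))
})

test_that("sweep planting raises local haplotype homozygosity", {
  cfg <- simConfig(seed = 37, n_variants = 400, n_chroms = 1,
                   n_diploids = 40)
  sim <- simulatePanels(cfg)
  locus <- 200L
  ihh_before <- integrateEhh(ehhCurve(sim$panels$POP1, locus, "all"))
  sim2 <- plantSignal(sim, list(type = "sweep", pop = "POP1",
                                locus = locus, freq = 0.9,
                                span_bp = 1e5), seed = 2)
  ihh_after <- integrateEhh(ehhCurve(sim2$panels$POP1, locus, "all"))
  expect_gt(ihh_after, ihh_before)
})

test_that("balanced planting creates a frequency-matched cluster", {
  cfg <- simConfig(seed = 41, n_variants = 300, n_chroms = 1,
                   n_diploids = 30)
  sim <- simulatePanels(cfg)
  locus <- 150L
  sim2 <- plantSignal(sim, list(type = "balanced", locus = locus,
                                n_neighbors = 6, span_bp = 4000),
                      seed = 3)
  panel <- sim2$panels$POP1
  f <- colMeans(haplotypes(panel))
  expect_equal(unname(f[locus]), 0.5)
  tr_after <- betaTrack(panel, window_bp = 4000)
  tr_before <- betaTrack(sim$panels$POP1, window_bp = 4000)
  v <- variantInfo(panel)
  expect_gt(trackLookup(tr_after, v$chrom[locus], v$pos[locus]),
            trackLookup(tr_before, v$chrom[locus], v$pos[locus]))
})

test_that("track shifts apply additively at the requested positions", {
  tr <- ScoreTrack("phylop", rep("chr1", 5), c(10L, 20L, 30L, 40L, 50L),
                   rep(0, 5), tail = "two_sided", provenance = "ingested")
  sh <- plantTrackShift(tr, c("chr1", "chr1"), c(20L, 40L), 3)
  expect_equal(trackLookup(sh, "chr1", c(10, 20, 30, 40, 50)),
               c(0, 3, 0, 3, 0))
})

test_that("the fixture bundle round-trips through every reader", {
  dir <- file.path(tempdir(), "bundle_test")
  cfg <- simConfig(seed = 47, n_variants = 600, n_chroms = 2,
                   n_diploids = 25,
                   planted_signals = list(
                     list(type = "differentiated", pop = "POP2",
                          region = 1, delta = 0.6),
                     list(type = "conserved_track", region = 2,
                          track = "phylop", offset = 3)))
  truth <- suppressMessages(writeFixtureBundle(cfg, dir, n_regions = 5,
                                               n_genes = 25))
  expect_equal(length(truth$planted_signals), 2L)
  expect_equal(truth$n_regions, 5L)

  panel <- suppressMessages(readHaplotypePanel(
    file.path(dir, "panel.vcf"), file.path(dir, "sample_map.tsv"),
    truth$target_population))
  expect_equal(nVariants(panel), 600L)
  gwas <- readGwas(file.path(dir, "gwas.tsv"))
  genes <- readGeneBed(file.path(dir, "genes.bed"))
  expect_equal(length(genes), 25L)
  tr <- readScoreTrack(file.path(dir, "tracks", "phylop.tsv"), "phylop",
                       tail = "two_sided")
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_equal(length(tree$tip.label), 8L)
  tips <- readTipStates(file.path(dir, "tip_states.tsv"))
  expect_equal(ncol(tips), 8L)
  reg <- readMeasureRegistry(file.path(dir, "registry.yaml"))
  expect_equal(reg, defaultMeasureRegistry())

  ## GWAS p-values clump back into exactly the planted regions
  regions <- suppressMessages(clumpRegions(gwas, panel))
  rl <- regionList(regions)
  truth_ids <- vapply(truth$regions, `[[`, character(1), "region_id")
  expect_setequal(names(rl), truth_ids)
  for (trg in truth$regions)
    expect_setequal(rl[[trg$region_id]]$member_id,
                    unlist(trg$members))

  ## the planted conserved region carries the track offset
  cons <- truth$planted_signals[[2]]
  r2 <- rl[[cons$region_id]]
  vals <- lookupTrackValues(tr, r2)
  expect_gt(mean(vals), 1.5)  # background 0, planted +3
})
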