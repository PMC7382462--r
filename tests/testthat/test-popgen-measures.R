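## ---------------------------------------------------------------------------
## Weir-Cockerham FST
## ---------------------------------------------------------------------------

test_that("theta-hat handles fixed differences and monomorphic sites", {
  expect_equal(weirCockerhamFst(50, 1, 0, 50, 0, 0), 1.0)
  expect_true(is.na(weirCockerhamFst(50, 0, 0, 30, 0, 0)))
  expect_true(is.na(weirCockerhamFst(10, 1, 0, 10, 1, 0)))
})

test_that("theta-hat matches the scalar variance-component oracle", {
  ## the worked example
  got <- weirCockerhamFst(10, 0.8, 0.2, 10, 0.3, 0.4)
  expect_equal(got, wcOracle(10, 0.8, 0.2, 10, 0.3, 0.4), tolerance = 1e-12)
  expect_equal(got, 0.3637992831541219, tolerance = 1e-9)
  ## 1000 random sites to 1e-12
  set.seed(21)
  for (i in 1:1000) {
    n1 <- sample(5:100, 1); n2 <- sample(5:100, 1)
    p1 <- round(runif(1), 3); p2 <- round(runif(1), 3)
    h1 <- round(runif(1, 0, 2 * min(p1, 1 - p1)), 3)
    h2 <- round(runif(1, 0, 2 * min(p2, 1 - p2)), 3)
    expect_equal(weirCockerhamFst(n1, p1, h1, n2, p2, h2),
                 wcOracle(n1, p1, h1, n2, p2, h2), tolerance = 1e-12)
  }
})

test_that("theta-hat is symmetric in populations and allele labels", {
  set.seed(5)
  n1 <- 12; n2 <- 30
  p1 <- 0.7; h1 <- 0.3; p2 <- 0.2; h2 <- 0.25
  expect_equal(weirCockerhamFst(n1, p1, h1, n2, p2, h2),
               weirCockerhamFst(n2, p2, h2, n1, p1, h1))
  ## relabeling ref/alt maps p -> 1-p, h unchanged
  expect_equal(weirCockerhamFst(n1, p1, h1, n2, p2, h2),
               weirCockerhamFst(n1, 1 - p1, h1, n2, 1 - p2, h2))
})

test_that("fstTrack scores shared variants from panel genotypes", {
  ## haplotypes giving known p and het frequencies
  a <- makePanel(rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 1)),
                 population = "A")
  b <- makePanel(rbind(c(0, 0), c(0, 1), c(0, 1), c(1, 0)),
                 population = "B")
  tr <- fstTrack(a, b)
  ## site 1: A p=0.75 h=0.5 (genotypes 2,1), B p=0.25 h=0.5
  expect_equal(trackLookup(tr, "chr1", 1000),
               weirCockerhamFst(2, 0.75, 0.5, 2, 0.25, 0.5))
})

## ---------------------------------------------------------------------------
## EHH family
## ---------------------------------------------------------------------------

test_that("EHH enumerates distinct extended haplotypes", {
  ## 4 carriers whose extensions over the next two markers are
  ## {00, 00, 01, 10}: EHH = C(2,2)/C(4,2) = 1/6
  H <- rbind(c(1, 0, 0),
             c(1, 0, 0),
             c(1, 0, 1),
             c(1, 1, 0),
             c(0, 1, 1),
             c(0, 0, 1))
  panel <- makePanel(H)
  curve <- ehhCurve(panel, 1, allele = 1)
  expect_equal(curve$ehh[curve$offsets == 0], 1.0)
  expect_equal(curve$ehh[curve$offsets == 2000], 1 / 6)
  ## weakly decreasing outward
  right <- curve$ehh[curve$offsets >= 0]
  expect_true(all(diff(right) <= 1e-12))
})

test_that("EHH degenerate cases: identical carriers, too few carriers", {
  H <- rbind(c(1, 1, 0, 1), c(1, 1, 0, 1), c(1, 1, 0, 1),
             c(0, 0, 1, 0), c(0, 1, 1, 0), c(0, 0, 0, 1))
  panel <- makePanel(H)
  cv <- ehhCurve(panel, 2, allele = 1)  # carriers of 1 at col 2
  expect_true(all(cv$ehh[cv$offsets >= 0] >= 0))
  ## carriers identical across the whole panel -> EHH 1 everywhere
  cv1 <- ehhCurve(panel, 1, allele = 1)
  expect_true(all(cv1$ehh == 1))
  expect_error(ehhCurve(makePanel(rbind(c(1, 0), c(0, 1), c(0, 0),
                                        c(0, 1))), 1, allele = 1),
               "carrier")
})

test_that("iHH integrates trapezoids up to the cutoff", {
  mk <- function(offsets, ehh)
    structure(list(core_id = "x", allele = 1, offsets = offsets,
                   ehh = ehh), class = "EhhCurve")
  ## 1.0@0, 0.5@1000, 0.04@2000: second segment excluded -> 750
  expect_equal(integrateEhh(mk(c(0, 1000, 2000), c(1, 0.5, 0.04))), 750)
  ## flat 1.0 over one side -> rectangle
  expect_equal(integrateEhh(mk(c(0, 1000), c(1, 1))), 1000)
  ## below cutoff immediately -> 0
  expect_equal(integrateEhh(mk(c(0, 500), c(1, 0.01))), 0)
  ## sides add
  expect_equal(integrateEhh(mk(c(-1000, 0, 1000), c(0.5, 1, 0.5))),
               2 * 750)
})

test_that("a marker all carriers share never refines the EHH curve", {
  set.seed(31)
  H <- matrix(rbinom(20 * 6, 1, 0.5), nrow = 20)
  H[, 3] <- rep(c(1, 0), each = 10)
  panel <- makePanel(H, pos = c(1000, 2000, 3000, 4000, 5000, 6000))
  c0 <- ehhCurve(panel, 3, allele = 1)
  ## insert at 4500 a column where all carriers of the core allele agree:
  ## EHH at every pre-existing offset is unchanged, and the new offset
  ## carries the value of the step it lands on
  H2 <- cbind(H[, 1:4], as.integer(H[, 3] == 1), H[, 5:6])
  panel2 <- makePanel(H2, pos = c(1000, 2000, 3000, 4000, 4500, 5000,
                                  6000))
  c1 <- ehhCurve(panel2, 3, allele = 1)
  shared <- intersect(c0$offsets, c1$offsets)
  expect_equal(c0$ehh[match(shared, c0$offsets)],
               c1$ehh[match(shared, c1$offsets)])
  expect_equal(c1$ehh[c1$offsets == 1500],
               c1$ehh[c1$offsets == 1000])
})

test_that("iHS flips sign under ancestral relabeling and standardizes", {
  set.seed(17)
  cfg <- simConfig(seed = 5, n_variants = 400, n_chroms = 1,
                   n_diploids = 40)
  sim <- simulatePanels(cfg)
  panel <- sim$panels$POP1
  ids <- variantInfo(panel)$id[51:60]
  anc0 <- sim$ancestral[ids]
  s0 <- suppressMessages(ihsScores(panel, anc0, variants = ids))
  anc1 <- 1L - anc0
  s1 <- suppressMessages(ihsScores(panel, anc1, variants = ids))
  ok <- !is.na(s0$unstd) & !is.na(s1$unstd)
  expect_true(any(ok))
  expect_equal(s0$unstd[ok], -s1$unstd[ok])

  ## standardized scores have per-bin mean 0, sd 1 by construction
  all_sc <- suppressMessages(ihsScores(panel, sim$ancestral))
  bin <- floor(all_sc$derived_freq / 0.025)
  for (b in unique(bin[!is.na(all_sc$ihs)])) {
    v <- all_sc$ihs[bin == b & !is.na(all_sc$ihs)]
    if (length(v) >= 10) {
      expect_equal(mean(v), 0, tolerance = 1e-9)
      expect_equal(sd(v), 1, tolerance = 1e-9)
    }
  }
})

test_that("XP-EHH is zero on identical panels and antisymmetric", {
  cfg <- simConfig(seed = 9, n_variants = 200, n_chroms = 1,
                   n_diploids = 30)
  sim <- simulatePanels(cfg)
  a <- sim$panels$POP1; b <- sim$panels$POP2
  ids <- variantInfo(a)$id[21:30]
  same <- xpehhScores(a, a, variants = ids)
  expect_true(all(same$raw[!is.na(same$raw)] == 0))
  ab <- xpehhScores(a, b, variants = ids)
  ba <- xpehhScores(b, a, variants = ids)
  ok <- !is.na(ab$raw) & !is.na(ba$raw)
  expect_true(any(ok))
  expect_equal(ab$raw[ok], -ba$raw[ok])
})

## ---------------------------------------------------------------------------
## Beta score
## ---------------------------------------------------------------------------

test_that("Beta matches the direct-summation oracle and its conventions", {
  expect_equal(betaScore(0.3, numeric(0), 10), 0)
  f_win <- c(0.3, 0.3, 0.1, 0.5, 0.2)
  expect_equal(betaScore(0.3, f_win, 10), betaOracle(0.3, f_win, 10),
               tolerance = 1e-12)
  ## adding a perfectly matched variant strictly increases beta
  expect_gt(betaScore(0.3, c(f_win, 0.3), 10), betaScore(0.3, f_win, 10))
})

test_that("Beta on neutral windows centers near zero", {
  ## neutral windows: S ~ Poisson(theta * a_n), frequencies from the
  ## 1/k site-frequency spectrum; beta is then mean-zero by construction
  set.seed(77)
  n <- 40
  theta <- 2
  an <- sum(1 / (1:(n - 1)))
  vals <- replicate(200, {
    S <- rpois(1, theta * an)
    f_core <- runif(1, 0.05, 0.5)
    k <- sample(1:(n - 1), S, replace = TRUE, prob = 1 / (1:(n - 1)))
    betaScore(f_core, pmin(k / n, 1 - k / n), n)
  })
  expect_lt(abs(mean(vals)), 0.5)
})

test_that("betaTrack windows exclude the core and respect chromosome", {
  H <- matrix(rbinom(20 * 4, 1, 0.5), nrow = 20)
  H[, 1] <- rep(c(0, 1), 10)
  panel <- makePanel(H, pos = c(100L, 300L, 450L, 5000L),
                     chrom = c("chr1", "chr1", "chr1", "chr1"))
  tr <- betaTrack(panel, window_bp = 1000L)
  f <- pmin(colMeans(H), 1 - colMeans(H))
  ## core at 100: window [<=600] holds positions 300, 450 only
  expect_equal(trackLookup(tr, "chr1", 100),
               betaScore(f[1], f[2:3], 20))
  ## isolated variant: empty window -> 0
  expect_equal(trackLookup(tr, "chr1", 5000), 0)
})

## ---------------------------------------------------------------------------
## Alignment block age
## ---------------------------------------------------------------------------

test_that("block age is the dated MRCA age", {
  tree <- ape::read.tree(text = "((H:5,C:5):5,G:10);")
  expect_equal(alignmentBlockAge(tree, c("H", "C"), "H"), 5)
  expect_equal(alignmentBlockAge(tree, c("H", "G"), "H"), 10)
  expect_equal(alignmentBlockAge(tree, c("H", "C", "G"), "H"), 10)
  expect_equal(alignmentBlockAge(tree, "H", "H"), 0)
  expect_error(alignmentBlockAge(tree, c("H", "X"), "H"), "X")
  expect_error(alignmentBlockAge(tree, c("C", "G"), "H"), "focal")
  bad <- ape::read.tree(text = "((H:5,C:2):5,G:10);")
  expect_error(alignmentBlockAge(bad, c("H", "C"), "H"), "ultrametric")
})

test_that("block age is monotone under adding species", {
  set.seed(13)
  tree <- ape::rcoal(10)
  tree$tip.label <- paste0("t", 1:10)
  for (i in 1:20) {
    sz <- sample(1:9, 1)
    block <- c("t1", sample(setdiff(tree$tip.label, "t1"), sz - 1))
    bigger <- unique(c(block, sample(tree$tip.label, 2)))
    expect_lte(alignmentBlockAge(tree, block, "t1"),
               alignmentBlockAge(tree, bigger, "t1") + 1e-12)
  }
})

test_that("track lookups over regions preserve missing markers", {
  tr <- ScoreTrack("m", c("chr1", "chr1"), c(1000L, 3000L), c(1, 3),
                   tail = "upper", provenance = "ingested")
  panel <- makePanel(matrix(rbinom(12, 1, 0.5), nrow = 4))
  region <- makeRegion(panel, 1, 2:3)
  vals <- lookupTrackValues(tr, region)
  expect_equal(vals, c(1, NA, 3))
  expect_equal(sum(is.na(vals)), 1L)
})
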