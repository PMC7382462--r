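library(GenomicRanges)

test_that("pool annotation computes the four matching covariates", {
  ## 200 haplotypes; column 1 carries 30 alt alleles -> maf 0.15
  set.seed(3)
  H <- cbind(c(rep(1, 30), rep(0, 170)),
             rbinom(200, 1, 0.4), rbinom(200, 1, 0.4))
  panel <- makePanel(H, pos = c(1000L, 2000L, 3000L))
  genes <- GRanges("chr1", IRanges(c(900, 40000), width = 500))
  ann <- annotatePool(panel, genes)
  expect_equal(ann$maf[ann$variant_id == "s001"], 0.15)
  ## variant at 1000 lies inside the gene [900, 1399] -> distance 0
  expect_equal(ann$gene_distance[ann$variant_id == "s001"], 0L)
  expect_true(all(ann$n_ld_buddies >= 0))
})

test_that("gene density equals a brute-force interval-overlap count", {
  panel <- makePanel(matrix(c(0, 1, 0, 1), 4, 1), pos = 50000L)
  starts <- c(10000, 49000, 99000, 200000)
  genes <- GRanges("chr1", IRanges(starts, width = 2000))
  ann <- annotatePool(panel, genes, density_window_bp = 100000L)
  win <- c(50000 - 50000, 50000 + 50000)
  oracle <- sum(starts <= win[2] & (starts + 1999) >= max(1, win[1]))
  expect_equal(ann$gene_density, oracle)
  expect_equal(oracle, 3L)
})

test_that("empty gene set errors; matching windows accept and reject", {
  panel <- makePanel(matrix(c(0, 1, 0, 1), 4, 1))
  expect_error(annotatePool(panel, GRanges()), "empty gene set")

  lead <- data.frame(variant_id = "L", chrom = "chr9", pos = 1e6,
                     maf = 0.20, n_ld_buddies = 20L, gene_density = 2L,
                     gene_distance = 1000L)
  mk <- function(id, maf, bud, den, dis)
    data.frame(variant_id = id, chrom = "chr1", pos = 5e6, maf = maf,
               n_ld_buddies = bud, gene_density = den, gene_distance = dis)
  pool <- rbind(
    mk("ok", 0.24, 22L, 2L, 5000L),     # all four windows satisfied
    mk("maf_out", 0.26, 20L, 2L, 1000L),  # |0.26-0.20| > 0.05
    mk("bud_out", 0.20, 23L, 2L, 1000L),  # 23 > 22 = 1.1 * 20
    mk("den_out", 0.20, 20L, 13L, 1000L), # 13 > 12 = 6 * 2
    mk("dup", 0.20, 20L, 2L, 1000L))      # exact duplicate of lead
  got <- selectControlLeads(lead, pool, n = 10, seed = 1)
  expect_setequal(got, c("ok", "dup"))
  expect_error(selectControlLeads(lead, pool[0, ], n = 10, seed = 1),
               "empty")
})

test_that("zero-valued covariates demand exact zero matches", {
  lead <- data.frame(variant_id = "L", chrom = "chr9", pos = 1e6,
                     maf = 0.30, n_ld_buddies = 0L, gene_density = 0L,
                     gene_distance = 0L)
  pool <- data.frame(variant_id = c("z", "nz"), chrom = "chr1",
                     pos = c(5e6, 6e6), maf = 0.30,
                     n_ld_buddies = c(0L, 1L), gene_density = 0L,
                     gene_distance = 0L)
  expect_equal(selectControlLeads(lead, pool, n = 5, seed = 1), "z")
})

test_that("control regions fill strictly, then relaxed, then missing", {
  ## columns: lead (1), 2 identical partners (r2 = 1), 5 weak partners
  ## (r2 in (0.6, 0.9)), plus independent noise columns
  set.seed(42)
  n <- 40
  lead <- rbinom(n, 1, 0.5)
  weak <- replicate(5, {
    x <- lead
    flip <- sample(n, 3)          # a few flips: r2 drops below 0.9
    x[flip] <- 1 - x[flip]
    x
  })
  H <- cbind(lead, lead, lead, weak)
  panel <- makePanel(H)
  r2s <- vapply(2:8, function(j) rSquared(panel, 1, j), numeric(1))
  expect_true(all(r2s[1:2] > 0.9))
  expect_true(all(r2s[3:7] > 0.6 & r2s[3:7] < 0.9))

  suite <- assembleControlRegions("R", "s001", k = 4, panel = panel,
                                  seed = 5)
  m <- controlMembers(suite)
  expect_equal(sum(m$matched_at == "0.9", na.rm = TRUE), 2L)
  expect_equal(sum(m$matched_at == "0.6", na.rm = TRUE), 2L)
  expect_equal(unname(matchFraction(suite)), 1.0)
})

test_that("partner shortfalls become missing members, not errors", {
  ## lead with no partners at all, k = 4: region of size 1, fraction 0.2
  set.seed(9)
  H <- cbind(rbinom(40, 1, 0.5), rbinom(40, 1, 0.5), rbinom(40, 1, 0.5))
  panel <- makePanel(H)
  r2s <- vapply(2:3, function(j) rSquared(panel, 1, j), numeric(1))
  expect_true(all(r2s < 0.6))
  suite <- assembleControlRegions("R", "s001", k = 4, panel = panel,
                                  seed = 5)
  expect_equal(unname(matchFraction(suite)), 0.2)
  expect_equal(sum(is.na(controlMembers(suite)$member_id)), 4L)
})

test_that("suites are reproducible by seed and distinct across seeds", {
  set.seed(1)
  H <- matrix(rbinom(60 * 40, 1, 0.5), nrow = 60)
  for (j in seq(2, 40, by = 2)) H[, j] <- H[, j - 1]  # paired LD
  panel <- makePanel(H)
  genes <- GRanges("chr1", IRanges(seq(1000, 39000, by = 8000),
                                   width = 2000))
  pool <- suppressMessages(annotatePool(panel, genes))
  region <- makeRegion(panel, 1, 2)
  s1 <- suppressMessages(buildControlSuite(region, pool, panel, 5, seed = 77,
                                           window_bp = 3000L))
  s2 <- suppressMessages(buildControlSuite(region, pool, panel, 5, seed = 77,
                                           window_bp = 3000L))
  s3 <- suppressMessages(buildControlSuite(region, pool, panel, 5, seed = 78,
                                           window_bp = 3000L))
  expect_identical(controlMembers(s1), controlMembers(s2))
  expect_false(identical(controlMembers(s1), controlMembers(s3)))
  ## every selected lead satisfies the matching windows, any seed
  lead_ann <- pool[pool$variant_id == "s001", ]
  for (s in list(s1, s3)) {
    leads <- controlMembers(s)$member_id[controlMembers(s)$matched_at ==
                                           "lead"]
    ca <- pool[match(leads, pool$variant_id), ]
    expect_true(all(abs(ca$maf - lead_ann$maf) <= 0.05))
    expect_true(all(ca$n_ld_buddies >= 0.9 * lead_ann$n_ld_buddies &
                    ca$n_ld_buddies <= 1.1 * lead_ann$n_ld_buddies))
    expect_false(any(leads %in% region$member_id))
  }
})

test_that("acceptance fraction factorises over iid covariates", {
  set.seed(123)
  N <- 4000
  pool <- data.frame(variant_id = paste0("v", 1:N), chrom = "chrX",
                     pos = seq_len(N) * 10, maf = runif(N, 0.01, 0.5),
                     n_ld_buddies = sample(5:40, N, replace = TRUE),
                     gene_density = sample(0:4, N, replace = TRUE),
                     gene_distance = sample(0:40000, N, replace = TRUE))
  lead <- data.frame(variant_id = "L", chrom = "chr9", pos = 1,
                     maf = 0.25, n_ld_buddies = 20L, gene_density = 2L,
                     gene_distance = 10000L)
  got <- suppressMessages(selectControlLeads(lead, pool, n = N, seed = 1))
  joint <- length(got) / N
  p_maf <- mean(abs(pool$maf - lead$maf) <= 0.05)
  p_bud <- mean(pool$n_ld_buddies >= 18 & pool$n_ld_buddies <= 22)
  p_den <- mean(pool$gene_density <= 12)
  p_dis <- mean(pool$gene_distance <= 60000)
  expect_lt(abs(joint - p_maf * p_bud * p_den * p_dis), 0.05)
})
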