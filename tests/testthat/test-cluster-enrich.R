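mkResults <- function(z_matrix) {
  regions <- rownames(z_matrix); measures <- colnames(z_matrix)
  do.call(rbind, lapply(regions, function(r)
    data.frame(region_id = r, measure = measures,
               observed_median = NA_real_, n_used = 100L, n_marked = 0L,
               p = NA_real_, z = z_matrix[r, ], removed = FALSE,
               stringsAsFactors = FALSE)))
}

test_that("z-matrix drops leaky measures and masks imputations", {
  z <- matrix(c(1, NA, NA, NA, NA,   # measure A: missing 80%
                0.5, 1, -1, 2, 0), ncol = 2,
              dimnames = list(paste0("r", 1:5), c("A", "B")))
  res <- mkResults(z)
  expect_message(zm <- buildZMatrix(res), "dropped")
  expect_equal(colnames(zValues(zm)), "B")
  expect_equal(zm@droppedMeasures, "A")
  ## complete matrix: nothing dropped, nothing masked
  z2 <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("r", 1:5),
                                                c("A", "B")))
  zm2 <- buildZMatrix(mkResults(z2))
  expect_false(any(imputationMask(zm2)))
  ## one missing cell -> imputed 0, masked
  z3 <- z2; z3[2, 1] <- NA
  zm3 <- buildZMatrix(mkResults(z3))
  expect_equal(zValues(zm3)[2, 1], 0)
  expect_true(imputationMask(zm3)[2, 1])
  expect_equal(sum(imputationMask(zm3)), 1L)
  ## all measures dropped is an error
  zna <- matrix(NA_real_, 4, 2, dimnames = list(paste0("r", 1:4),
                                                c("A", "B")))
  expect_error(suppressMessages(buildZMatrix(mkResults(zna))), "all")
})

test_that("extreme regions need a real |z| >= 1.5, never an imputed one", {
  z <- matrix(c(0.2, -1.6, 1.4, 0.3, NA, 0.1, NA, NA), ncol = 2,
              byrow = TRUE,
              dimnames = list(paste0("r", 1:4), c("A", "B")))
  zm <- buildZMatrix(mkResults(z))
  expect_equal(extremeRegions(zm), "r1")
  ## r4 is fully imputed: its 0 cells never qualify at any threshold
  expect_false("r4" %in% extremeRegions(zm, threshold = 0))
  expect_setequal(extremeRegions(zm, threshold = 0.1),
                  c("r1", "r2", "r3"))
})

test_that("clustering is deterministic, permutation-invariant, cut-sensitive", {
  set.seed(19)
  z <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("r", 1:10), paste0("m", 1:4)))
  z[2, ] <- z[1, ]                     # identical pair
  zm <- buildZMatrix(mkResults(z))
  cl <- clusterRegions(zm, cut_height = 2)
  expect_equal(unname(cl["r1"]), unname(cl["r2"]))
  expect_identical(cl, clusterRegions(zm, cut_height = 2))
  ## permutation of rows renames labels but preserves the partition
  perm <- sample(10)
  zmp <- buildZMatrix(mkResults(z[perm, ]))
  clp <- clusterRegions(zmp, cut_height = 2)
  same <- outer(cl, cl, "==")
  same_p <- outer(clp[names(cl)], clp[names(cl)], "==")
  expect_true(all(same == same_p))
  ## degenerate cuts
  singletons <- clusterRegions(zm, cut_height = 0)
  expect_equal(length(unique(singletons)), 9L)  # r1 == r2 collapse
  expect_equal(length(unique(clusterRegions(zm, cut_height = Inf))), 1L)
  ## two far rows split at a cut below their distance
  z2 <- rbind(a = c(0, 0), b = c(10, 0))
  colnames(z2) <- c("A", "B")
  zm2 <- buildZMatrix(mkResults(z2))
  expect_equal(length(unique(clusterRegions(zm2, cut_height = 7))), 2L)
  expect_equal(length(unique(clusterRegions(zm2, cut_height = 11))), 1L)
})

test_that("binomial null arithmetic is exact", {
  bn <- binomialNull(215)
  expect_identical(bn$expected, 215 * 0.05)
  expect_equal(bn$expected, 10.75)
  ## survival probabilities match explicit mass summation to 1e-12
  for (obs in c(5L, 11L, 26L)) {
    p <- binomialNull(215, obs)$p
    direct <- sum(vapply(obs:215, function(k)
      choose(215, k) * 0.05^k * 0.95^(215 - k), numeric(1)))
    expect_equal(p, direct, tolerance = 1e-12)
  }
})

test_that("genome-wide enrichment calibrates and detects plantings", {
  set.seed(55)
  pool <- rnorm(20000)
  ## null trait set drawn from the pool generator
  trait <- rnorm(215)
  rep_null <- genomewideEnrichment(trait, pool, n_random = 5000,
                                   n_iter = 200, seed = 31)
  expect_equal(rep_null$binomial_expected, 10.75)
  sd_bin <- sqrt(215 * 0.05 * 0.95)
  expect_lt(abs(rep_null$observed_count - 10.75), 3 * sd_bin)
  expect_true(rep_null$null_q05 <= rep_null$observed_count + 1e-9)
  expect_true(rep_null$null_q95 >= rep_null$observed_count - 1e-9)
  ## 20 of 100 planted above the pool's 95th percentile
  hi <- quantile(pool, 0.95) + 5
  trait2 <- c(rnorm(80), rep(hi, 20))
  rep_alt <- genomewideEnrichment(trait2, pool, n_random = 5000,
                                  n_iter = 100, seed = 32)
  expect_gte(rep_alt$observed_count, 20)
  expect_error(genomewideEnrichment(trait, rnorm(100), n_random = 5000,
                                    n_iter = 10, seed = 1), "pool")
})

test_that("enrichment count noise shrinks with more random regions", {
  ## drawing more random regions per iteration stabilises the genome-wide
  ## percentile, so the iteration-to-iteration count spread narrows
  set.seed(66)
  trait <- rnorm(100)
  spread <- vapply(c(300, 30000), function(np) {
    pool <- rnorm(np)
    r <- genomewideEnrichment(trait, pool, n_random = np / 2,
                              n_iter = 150, seed = 9)
    r$null_q95 - r$null_q05
  }, numeric(1))
  expect_lte(spread[2], spread[1])
})

test_that("matched enrichment counts significant regions against its null", {
  ## all trait p-values 1: never significant, never flagged
  gen_unif <- function(seed) withr::with_seed(seed, runif(50))
  r0 <- matchedEnrichment(rep(1, 50), gen_unif, n_iter = 50, seed = 3)
  expect_equal(r0$observed_count, 0L)
  expect_false(r0$flagged)
  ## planted: 15 of 50 regions significant -> flagged
  trait_p <- c(rep(0.001, 15), runif(35))
  r1 <- matchedEnrichment(trait_p, gen_unif, n_iter = 100, seed = 3)
  expect_gte(r1$observed_count, 15L)
  expect_true(r1$flagged)
  ## NA p never counts
  r2 <- matchedEnrichment(c(NA, NA, 0.01), gen_unif, n_iter = 20,
                          seed = 3)
  expect_equal(r2$observed_count, 1L)
})

test_that("matched enrichment is calibrated on null trait sets", {
  gen_unif <- function(seed) withr::with_seed(seed, runif(40))
  flags <- vapply(1:40, function(i) {
    trait_p <- withr::with_seed(1000 + i, runif(40))
    matchedEnrichment(trait_p, gen_unif, n_iter = 60,
                      seed = 2000 + i)$flagged
  }, logical(1))
  expect_lte(sum(flags), 5L)
})
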