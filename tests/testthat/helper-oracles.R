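## Independent oracles used to check the implementation by a second route.

## Weir-Cockerham variance components computed scalar-by-scalar from the
## general r-population sums (spreadsheet style), independent of the
## vectorized two-population implementation.
wcOracle <- function(n1, p1, h1, n2, p2, h2) {
  n <- c(n1, n2); p <- c(p1, p2); h <- c(h1, h2)
  r <- 2
  nsum <- 0; for (i in 1:r) nsum <- nsum + n[i]
  nbar <- nsum / r
  nsq <- 0; for (i in 1:r) nsq <- nsq + n[i]^2
  nc <- (nsum - nsq / nsum) / (r - 1)
  pbar <- 0; for (i in 1:r) pbar <- pbar + n[i] * p[i] / nsum
  s2 <- 0; for (i in 1:r) s2 <- s2 + n[i] * (p[i] - pbar)^2 / ((r - 1) * nbar)
  hbar <- 0; for (i in 1:r) hbar <- hbar + n[i] * h[i] / nsum
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

## Exhaustive minimum-change labeling search over all internal-node state
## assignments of a rooted tree (5-state alphabet, unit cost).
exhaustiveSankoff <- function(tree, states, alphabet = c("A", "C", "G",
                                                         "T", "-")) {
  ntip <- length(tree$tip.label)
  n_int <- tree$Nnode
  combos <- as.matrix(expand.grid(rep(list(seq_along(alphabet)), n_int)))
  cost <- numeric(nrow(combos))
  tip_state <- match(states[tree$tip.label], alphabet)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L] - ntip
    ch <- tree$edge[e, 2L]
    if (ch <= ntip) {
      ts <- tip_state[ch]
      if (!is.na(ts)) cost <- cost + (combos[, par] != ts)
    } else {
      cost <- cost + (combos[, par] != combos[, ch - ntip])
    }
  }
  best <- min(cost)
  opt <- combos[cost == best, , drop = FALSE]
  sets <- lapply(seq_len(n_int), function(k)
    alphabet[sort(unique(opt[, k]))])
  names(sets) <- paste0("node", seq_len(n_int) + ntip)
  list(score = as.integer(best), internal_sets = sets)
}

## Direct-summation Beta(1) oracle
betaOracle <- function(f_core, f_window, n) {
  S <- length(f_window)
  if (S == 0) return(0)
  sw <- 0
  for (f in f_window) sw <- sw + (1 - abs(f - f_core) / 0.5)
  Ew <- 0; an <- 0
  for (k in 1:(n - 1)) {
    fk <- min(k / n, 1 - k / n)
    Ew <- Ew + (1 / k) * (1 - abs(fk - f_core) / 0.5)
    an <- an + 1 / k
  }
  sw / Ew - S / an
}

## random rooted binary tree with unit-ish branch lengths
randomTree <- function(n_tips) {
  tr <- ape::rtree(n_tips)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}
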