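## Per-variant evolutionary measures computed from haplotype panels:
## Weir-Cockerham FST, the EHH family (EHH, iHH, iHS, iES, XP-EHH),
## the Beta(1) balancing-selection score, and alignment block age.
## Ingested measures (PhyloP, PhastCons, GERP, LINSIGHT, TMRCA) enter as
## ScoreTracks through readScoreTrack() and share the same interface.

## ---------------------------------------------------------------------------
## Weir-Cockerham FST
## ---------------------------------------------------------------------------

#' Weir-Cockerham theta-hat for two populations
#'
#' Per-site variance-component estimator of FST between two populations
#' (r = 2), from diploid sample sizes, alt-allele frequencies and observed
#' heterozygote frequencies. Vectorized over sites. Sites monomorphic
#' overall (a + b + c = 0) return `NA`. Symmetric under swapping
#' populations and invariant under ref/alt relabeling.
#'
#' @param n1,n2 Diploid sample sizes (>= 2).
#' @param p1,p2 Alt-allele frequencies.
#' @param h1,h2 Observed heterozygote frequencies.
#' @return Numeric vector of theta-hat values (`NA` where undefined).
#' @export
weirCockerhamFst <- function(n1, p1, h1, n2, p2, h2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  ifelse(denom == 0, NA_real_, a / denom)
}

## per-sample genotype summaries from a phased panel
.panelGenoStats <- function(panel) {
  H <- haplotypes(panel)
  n_dip <- nrow(H) / 2L
  g <- H[seq(1L, nrow(H), by = 2L), , drop = FALSE] +
       H[seq(2L, nrow(H), by = 2L), , drop = FALSE]
  list(n = n_dip, p = colMeans(H), h = colMeans(g == 1L))
}

#' Per-variant FST track between two panels
#'
#' @param panelA,panelB [HaplotypePanel-class] objects; variants are matched
#'   by id and only shared variants are scored.
#' @return A [ScoreTrack-class] named `"fst"` (upper tail, computed);
#'   overall-monomorphic sites are absent from the track.
#' @export
fstTrack <- function(panelA, panelB) {
  va <- variantInfo(panelA); vb <- variantInfo(panelB)
  shared <- intersect(va$id, vb$id)
  ia <- match(shared, va$id); ib <- match(shared, vb$id)
  sa <- .panelGenoStats(panelA); sb <- .panelGenoStats(panelB)
  theta <- weirCockerhamFst(sa$n, sa$p[ia], sa$h[ia],
                            sb$n, sb$p[ib], sb$h[ib])
  ok <- !is.na(theta)
  ScoreTrack("fst", va$chrom[ia][ok], va$pos[ia][ok], theta[ok],
             tail = "upper", provenance = "computed")
}

## ---------------------------------------------------------------------------
## EHH family
## ---------------------------------------------------------------------------

#' Extended haplotype homozygosity curve around a core variant
#'
#' At signed physical offset x from the core, EHH is the probability that
#' two randomly drawn carrier haplotypes are identical over all markers
#' between the core (exclusive) and x (inclusive):
#' \eqn{\sum_h \binom{n_h}{2} / \binom{n}{2}} over distinct extended
#' haplotypes h. The curve is computed marker-by-marker outward in both
#' directions, is 1 at offset 0, and weakly decreases outward. With
#' `allele = "all"` the curve is the site-specific EHHS over all haplotypes
#' used for iES.
#'
#' @param panel A [HaplotypePanel-class].
#' @param core Variant column index or id.
#' @param allele `0`, `1`, or `"all"` — which carrier class to follow.
#' @param stop_below Stop extending a side once EHH drops strictly below
#'   this value (0 retains the full curve until EHH reaches 0).
#' @return An object of class `EhhCurve`: list with `core_id`, `allele`,
#'   `offsets` (sorted, 0 included) and `ehh`.
#' @export
ehhCurve <- function(panel, core, allele = "all", stop_below = 0) {
  v <- variantInfo(panel)
  H <- haplotypes(panel)
  if (is.character(core)) core <- match(core, v$id)
  carriers <- if (identical(allele, "all")) seq_len(nrow(H)) else
    which(H[, core] == allele)
  n <- length(carriers)
  if (n < 2L) stop("fewer than 2 carrier haplotypes at core")
  nC2 <- choose(n, 2L)
  chrom_cols <- which(v$chrom == v$chrom[core])
  core_pos <- v$pos[core]

  side <- function(cols) {
    grp <- rep(1L, n)
    offs <- numeric(0)
    vals <- numeric(0)
    for (j in cols) {
      grp <- as.integer(factor(paste(grp, H[carriers, j])))
      val <- sum(choose(tabulate(grp), 2L)) / nC2
      offs <- c(offs, v$pos[j] - core_pos)
      vals <- c(vals, val)
      if (val == 0 || val < stop_below) break
    }
    list(offs = offs, vals = vals)
  }
  right <- side(chrom_cols[chrom_cols > core])
  left <- side(rev(chrom_cols[chrom_cols < core]))
  o <- c(rev(left$offs), 0, right$offs)
  e <- c(rev(left$vals), 1, right$vals)
  structure(list(core_id = v$id[core], allele = allele,
                 offsets = o, ehh = e), class = "EhhCurve")
}

#' Integrated EHH (iHH) with a homozygosity cutoff
#'
#' Trapezoidal area under the EHH curve on each side of the core,
#' accumulating consecutive segments while both endpoints are >= `cutoff`
#' and stopping at the first endpoint below it; the two sides add.
#'
#' @param curve An [ehhCurve()] result.
#' @param cutoff EHH cutoff (default 0.05).
#' @return Non-negative area in bp-scaled EHH units.
#' @export
integrateEhh <- function(curve, cutoff = 0.05) {
  o <- curve$offsets
  e <- curve$ehh
  sideArea <- function(offs, vals) {
    ## offs ascending in |offset|, starting at the core (0, value 1)
    offs <- c(0, offs); vals <- c(1, vals)
    area <- 0
    for (k in seq_len(length(offs) - 1L)) {
      if (vals[k] < cutoff || vals[k + 1L] < cutoff) break
      area <- area + (vals[k] + vals[k + 1L]) / 2 * abs(offs[k + 1L] - offs[k])
    }
    area
  }
  right <- o > 0
  left <- o < 0
  sideArea(o[right], e[right]) +
    sideArea(rev(-o[left]), rev(e[left]))
}

#' Integrated haplotype score (iHS)
#'
#' Per variant: unstandardized iHS = ln(iHH_ancestral / iHH_derived), with
#' iHH integrated to the EHH `cutoff`; standardized within derived-allele
#' frequency bins of width `bin_width` (subtract bin mean, divide by bin
#' sd). Bins with fewer than `min_bin` scored variants yield `NA`. Variants
#' with unknown ancestral allele, a fixed allele class, fewer than 2
#' carriers of either allele, or zero iHH are `NA` (logged).
#'
#' @param panel A [HaplotypePanel-class].
#' @param ancestral Named vector (variant id -> ancestral allele coded 0/1
#'   on the panel's ref/alt coding).
#' @param bin_width Derived-frequency bin width (default 0.025).
#' @param min_bin Minimum variants per bin for standardization.
#' @param cutoff EHH integration cutoff.
#' @param variants Optional variant ids to score (default: all with known
#'   ancestral allele).
#' @return `data.frame`: `variant_id`, `derived_freq`, `ihh_anc`,
#'   `ihh_der`, `unstd`, `ihs`.
#' @export
ihsScores <- function(panel, ancestral, bin_width = 0.025, min_bin = 10L,
                      cutoff = 0.05, variants = NULL) {
  v <- variantInfo(panel)
  H <- haplotypes(panel)
  ids <- if (is.null(variants)) intersect(v$id, names(ancestral)) else
    variants
  cols <- match(ids, v$id)
  stopifnot(!anyNA(cols))
  res <- data.frame(variant_id = ids, derived_freq = NA_real_,
                    ihh_anc = NA_real_, ihh_der = NA_real_,
                    unstd = NA_real_, ihs = NA_real_,
                    stringsAsFactors = FALSE)
  n_skipped <- 0L
  for (k in seq_along(cols)) {
    i <- cols[k]
    anc <- ancestral[[ids[k]]]
    der <- 1L - anc
    p_der <- mean(H[, i] == der)
    res$derived_freq[k] <- p_der
    if (p_der <= 0 || p_der >= 1) { n_skipped <- n_skipped + 1L; next }
    if (sum(H[, i] == anc) < 2L || sum(H[, i] == der) < 2L) {
      n_skipped <- n_skipped + 1L; next
    }
    iha <- integrateEhh(ehhCurve(panel, i, anc, stop_below = cutoff), cutoff)
    ihd <- integrateEhh(ehhCurve(panel, i, der, stop_below = cutoff), cutoff)
    res$ihh_anc[k] <- iha
    res$ihh_der[k] <- ihd
    if (ihd == 0 || iha == 0) { n_skipped <- n_skipped + 1L; next }
    res$unstd[k] <- log(iha / ihd)
  }
  if (n_skipped)
    message("ihsScores: ", n_skipped, " variant(s) unscored")
  bin <- floor(res$derived_freq / bin_width)
  ok <- !is.na(res$unstd)
  for (b in unique(bin[ok])) {
    in_bin <- ok & bin == b
    if (sum(in_bin) < min_bin) next
    mu <- mean(res$unstd[in_bin])
    sdv <- stats::sd(res$unstd[in_bin])
    if (sdv > 0) res$ihs[in_bin] <- (res$unstd[in_bin] - mu) / sdv
  }
  res
}

#' Site-specific integrated EHH (iES) per variant
#'
#' EHHS over all haplotypes, integrated with the standard cutoff.
#'
#' @inheritParams ihsScores
#' @return `data.frame`: `variant_id`, `ies`.
#' @export
iesScores <- function(panel, cutoff = 0.05, variants = NULL) {
  v <- variantInfo(panel)
  ids <- if (is.null(variants)) v$id else variants
  cols <- match(ids, v$id)
  ies <- vapply(cols, function(i)
    integrateEhh(ehhCurve(panel, i, "all", stop_below = cutoff), cutoff),
    numeric(1L))
  data.frame(variant_id = ids, ies = ies, stringsAsFactors = FALSE)
}

#' Cross-population EHH score (XP-EHH)
#'
#' Per shared polymorphic variant, raw XP-EHH = ln(iES_A / iES_B);
#' standardized over all scored variants (subtract mean, divide by sd).
#' Positive values mean longer haplotype homozygosity in population A.
#'
#' @param panelA,panelB [HaplotypePanel-class] objects.
#' @param cutoff EHH integration cutoff.
#' @param variants Optional variant ids to score.
#' @return `data.frame`: `variant_id`, `ies_a`, `ies_b`, `raw`, `xpehh`.
#' @export
xpehhScores <- function(panelA, panelB, cutoff = 0.05, variants = NULL) {
  va <- variantInfo(panelA); vb <- variantInfo(panelB)
  pa <- colMeans(haplotypes(panelA)); pb <- colMeans(haplotypes(panelB))
  shared <- intersect(va$id[pa > 0 & pa < 1], vb$id[pb > 0 & pb < 1])
  ids <- if (is.null(variants)) shared else intersect(variants, shared)
  ies_a <- iesScores(panelA, cutoff, ids)$ies
  ies_b <- iesScores(panelB, cutoff, ids)$ies
  raw <- ifelse(ies_b == 0 | ies_a == 0, NA_real_, log(ies_a / ies_b))
  ok <- !is.na(raw)
  std <- rep(NA_real_, length(raw))
  if (sum(ok) >= 2L && stats::sd(raw[ok]) > 0)
    std[ok] <- (raw[ok] - mean(raw[ok])) / stats::sd(raw[ok])
  data.frame(variant_id = ids, ies_a = ies_a, ies_b = ies_b, raw = raw,
             xpehh = std, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Beta score (balancing selection)
## ---------------------------------------------------------------------------

#' Beta(1) score for one core variant
#'
#' Excess of nearby variants at folded frequencies similar to the core's:
#' each window variant contributes similarity weight
#' \eqn{w_i = 1 - |f_i - f_c| / 0.5} (folded frequencies; 0.5 is the
#' maximum possible difference). Then
#' \eqn{\hat\theta_\beta = \sum_i w_i / E_w} with
#' \eqn{E_w = \sum_{k=1}^{n-1} (1/k)\, w(\mathrm{fold}(k/n), f_c)} the
#' neutral expectation of summed weight per unit theta,
#' \eqn{\hat\theta_W = S / \sum_{k=1}^{n-1} 1/k} Watterson's estimator on
#' the S window variants, and \eqn{\beta = \hat\theta_\beta - \hat\theta_W}.
#' An empty window gives 0 by convention.
#'
#' @param f_core Core folded frequency in (0, 0.5].
#' @param f_window Folded frequencies of window variants (core excluded).
#' @param n Haplotype sample size.
#' @return The Beta(1) value.
#' @export
betaScore <- function(f_core, f_window, n) {
  stopifnot(f_core > 0, f_core <= 0.5, n >= 2)
  S <- length(f_window)
  if (S == 0L) return(0)
  stopifnot(all(f_window > 0), all(f_window <= 0.5))
  w <- 1 - abs(f_window - f_core) / 0.5
  k <- seq_len(n - 1L)
  fold_k <- pmin(k / n, 1 - k / n)
  Ew <- sum((1 / k) * (1 - abs(fold_k - f_core) / 0.5))
  an <- sum(1 / k)
  sum(w) / Ew - S / an
}

#' Per-variant Beta track for a panel
#'
#' Scores every polymorphic variant against the folded frequencies of the
#' other polymorphic variants within `window_bp` (total window width,
#' centered on the core).
#'
#' @param panel A [HaplotypePanel-class].
#' @param window_bp Total window width in bp (default 1000).
#' @return A [ScoreTrack-class] named `"beta"` (upper tail, computed).
#' @export
betaTrack <- function(panel, window_bp = 1000L) {
  v <- variantInfo(panel)
  H <- haplotypes(panel)
  n <- nrow(H)
  p <- colMeans(H)
  poly <- p > 0 & p < 1
  fold <- pmin(p, 1 - p)
  half <- window_bp / 2
  idx <- which(poly)
  beta <- vapply(idx, function(i) {
    win <- which(poly & v$chrom == v$chrom[i] &
                 abs(v$pos - v$pos[i]) <= half)
    win <- setdiff(win, i)
    betaScore(fold[i], fold[win], n)
  }, numeric(1L))
  ScoreTrack("beta", v$chrom[idx], v$pos[idx], beta,
             tail = "upper", provenance = "computed")
}

## ---------------------------------------------------------------------------
## Alignment block age
## ---------------------------------------------------------------------------

#' Age of the MRCA of an alignment block's species
#'
#' On a time-calibrated (ultrametric) species tree, the age in Myr of the
#' most recent common ancestor of the species present in a multiple-
#' alignment block containing the focal species. A block containing only
#' the focal species has age 0. Adding species to a block never decreases
#' the age.
#'
#' @param tree An `ape::phylo` with branch lengths in Myr; must be
#'   ultrametric within tolerance.
#' @param block_species Character vector of species in the block.
#' @param focal The focal species; must be in the block and the tree.
#' @param tol Ultrametricity tolerance on tip depths.
#' @return Age in Myr.
#' @export
alignmentBlockAge <- function(tree, block_species, focal, tol = 1e-6) {
  missing_sp <- setdiff(c(block_species, focal), tree$tip.label)
  if (length(missing_sp))
    stop("species not in tree: ", paste(missing_sp, collapse = ", "))
  if (!focal %in% block_species)
    stop("focal species must be in the block")
  depths <- ape::node.depth.edgelength(tree)
  tip_depths <- depths[seq_along(tree$tip.label)]
  if (diff(range(tip_depths)) > tol * max(1, max(tip_depths)))
    stop("tree is not ultrametric: ages undefined")
  height <- max(tip_depths)
  block_species <- unique(block_species)
  if (length(block_species) == 1L) return(0)
  mrca <- ape::getMRCA(tree, block_species)
  height - depths[mrca]
}

## ---------------------------------------------------------------------------
## Track lookup over regions
## ---------------------------------------------------------------------------

#' Per-member track values for a region
#'
#' @param track A [ScoreTrack-class].
#' @param region One region's `data.frame` (an element of [regionList()]).
#' @return Numeric vector in region member order; `NA` where the track has
#'   no value (missing is preserved, never imputed).
#' @export
lookupTrackValues <- function(track, region) {
  trackLookup(track, region$chrom, region$pos)
}
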