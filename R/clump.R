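## LD computation on phased haplotype panels and greedy LD clumping of GWAS
## summary statistics into disjoint lead + partner trait regions.

## r^2 of column i against columns js of a 0/1 haplotype matrix.
## Monomorphic target columns yield NA.
.r2Vector <- function(H, i, js) {
  n <- nrow(H)
  x <- H[, i]
  pA <- mean(x)
  if (pA == 0 || pA == 1) stop("monomorphic column: LD undefined")
  Y <- H[, js, drop = FALSE]
  pB <- colMeans(Y)
  pAB <- as.numeric(crossprod(x, Y)) / n
  D <- pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  out <- ifelse(denom > 0, D^2 / denom, NA_real_)
  names(out) <- colnames(Y)
  out
}

## Full r^2 matrix of a 0/1 haplotype matrix (all columns polymorphic
## assumed; monomorphic columns give NA rows/cols).
.r2Matrix <- function(H) {
  n <- nrow(H)
  p <- colMeans(H)
  pAB <- crossprod(H) / n
  D <- pAB - outer(p, p)
  pq <- p * (1 - p)
  denom <- outer(pq, pq)
  r2 <- D^2 / denom
  r2[denom == 0] <- NA_real_
  r2
}

#' Haplotype r-squared between two panel variants
#'
#' Standard haplotype LD: \eqn{r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))} with
#' \eqn{D = p_{AB} - p_A p_B}, computed from phased 0/1 columns. Symmetric
#' in its arguments and invariant under swapping allele labels at either
#' site.
#'
#' @param panel A [HaplotypePanel-class].
#' @param i,j Variant column indices or variant ids.
#' @return r-squared in `[0, 1]`.
#' @export
rSquared <- function(panel, i, j) {
  H <- haplotypes(panel)
  if (is.character(i)) i <- match(i, variantInfo(panel)$id)
  if (is.character(j)) j <- match(j, variantInfo(panel)$id)
  pj <- mean(H[, j])
  if (pj == 0 || pj == 1) stop("monomorphic column: LD undefined")
  unname(.r2Vector(H, i, j))
}

#' Clumping configuration
#'
#' Defaults follow the region-construction settings used throughout the
#' framework: lead and member p-value thresholds of 1e-4, region membership
#' at r^2 > 0.9 to the lead, and a 250 kb window around the lead.
#'
#' @param p_lead,p_member P-value thresholds in (0, 1].
#' @param r2_region r-squared threshold in `[0, 1]` for region membership.
#' @param window_bp Half-window in bp around the lead.
#' @return A list of class `ClumpConfig`.
#' @export
clumpConfig <- function(p_lead = 1e-4, p_member = 1e-4, r2_region = 0.9,
                        window_bp = 250000L) {
  stopifnot(p_lead > 0, p_lead <= 1, p_member > 0, p_member <= 1,
            r2_region >= 0, r2_region <= 1, window_bp > 0)
  structure(list(p_lead = p_lead, p_member = p_member,
                 r2_region = r2_region, window_bp = as.integer(window_bp)),
            class = "ClumpConfig")
}

#' Greedy LD clumping of GWAS variants into trait regions
#'
#' Repeatedly takes the lowest-p unassigned variant with `p <= p_lead` as a
#' region lead, then assigns every unassigned variant within `window_bp` of
#' the lead with `p <= p_member` and `r^2 > r2_region` to the lead's region.
#' Regions are disjoint; ties in p are broken by (chrom, pos) ascending so
#' the output is invariant to input row order. GWAS variants absent from the
#' panel are skipped with a logged count.
#'
#' @param gwas `data.frame` with `variant_id`, `chrom`, `pos`, `p` (see
#'   [readGwas()]).
#' @param panel [HaplotypePanel-class] used for all LD.
#' @param cfg A [clumpConfig()].
#' @return `data.frame` with one row per region member: `region_id` (the
#'   lead variant id), `member_id`, `chrom`, `pos`, `p`, `r2_to_lead`,
#'   `is_lead`. Zero rows when no variant passes `p_lead`.
#' @export
clumpRegions <- function(gwas, panel, cfg = clumpConfig()) {
  v <- variantInfo(panel)
  H <- haplotypes(panel)
  idx <- match(gwas$variant_id, v$id)
  absent <- is.na(idx)
  if (any(absent))
    message("clumpRegions: skipped ", sum(absent),
            " GWAS variant(s) absent from panel")
  g <- gwas[!absent, , drop = FALSE]
  g$col <- idx[!absent]
  g <- g[order(g$p, g$chrom, g$pos), , drop = FALSE]

  empty <- data.frame(region_id = character(), member_id = character(),
                      chrom = character(), pos = integer(), p = numeric(),
                      r2_to_lead = numeric(), is_lead = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(g) == 0L) return(empty)

  assigned <- rep(FALSE, nrow(g))
  freq <- colMeans(H)
  out <- list()
  repeat {
    lead_i <- which(!assigned & g$p <= cfg$p_lead)[1L]
    if (is.na(lead_i)) break
    assigned[lead_i] <- TRUE
    lead <- g[lead_i, ]
    cand <- which(!assigned & g$p <= cfg$p_member &
                  g$chrom == lead$chrom &
                  abs(g$pos - lead$pos) <= cfg$window_bp)
    members <- integer()
    r2m <- numeric()
    lead_poly <- freq[lead$col] > 0 && freq[lead$col] < 1
    if (length(cand) && lead_poly) {
      r2 <- .r2Vector(H, lead$col, g$col[cand])
      keep <- !is.na(r2) & r2 > cfg$r2_region
      members <- cand[keep]
      r2m <- r2[keep]
    }
    assigned[members] <- TRUE
    rows <- c(lead_i, members)
    out[[length(out) + 1L]] <- data.frame(
      region_id = lead$variant_id, member_id = g$variant_id[rows],
      chrom = g$chrom[rows], pos = g$pos[rows], p = g$p[rows],
      r2_to_lead = c(1.0, unname(r2m)),
      is_lead = c(TRUE, rep(FALSE, length(members))),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split a region table into a per-region list
#'
#' @param regions Output of [clumpRegions()].
#' @return Named list of per-region `data.frame`s, keyed by `region_id`.
#' @export
regionList <- function(regions) {
  split(regions, factor(regions$region_id, levels = unique(regions$region_id)))
}
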