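---
title: "Quantifying evolutionary forces on trait-associated genomic regions"
author: "evoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying evolutionary forces on trait-associated genomic regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoreg)
```

## The problem

Genome-wide association studies identify regions whose variants associate
with a complex trait, but say nothing about the evolutionary forces that
shaped those regions. Classical selection scans (iHS, XP-EHH, F~ST~
outliers, Beta) rank loci genome-wide; a trait-associated region that is
merely *unusual for its own allele-frequency and LD profile* can be missed,
and a region that looks extreme genome-wide can be ordinary once its profile
is accounted for, because most evolutionary measures covary strongly with
minor allele frequency (MAF) and linkage disequilibrium (LD) — the same
quantities that drive GWAS power.

`evoreg` implements a matched-null framework. Each trait-associated region
is compared not to the genome at large but to thousands of control regions
matched on MAF, LD and gene architecture. This yields, per region and per
evolutionary measure, an empirical p-value and a z-score on a common scale,
which can then be clustered into signature groups and tested for set-level
enrichment.

## The procedure

1. **Region construction.** GWAS summary statistics are greedily LD-clumped:
   the lowest-p unassigned variant with p ≤ 10^-4^ becomes a lead; every
   unassigned variant within 250 kb with p ≤ 10^-4^ and r² > 0.9 to the
   lead joins its region. Regions are disjoint; ties in p break by
   coordinate, so the output is independent of input order. All LD is
   haplotype r² computed on the phased panel of the target population.

2. **Matched controls.** Every panel variant is annotated with four
   covariates: folded MAF, LD-buddy count (variants at r² > 0.9 within the
   clump window), gene density (genes overlapping a 100 kb centered window)
   and distance to the nearest gene. For each trait lead, up to 5000
   control leads are drawn from variants matching on all four: MAF within
   ±0.05 (absolute), buddies within ±10% (relative), density and distance
   within ±500% (relative, floored at 0). A relative MAF window would be
   far tighter than the intended percentage-point semantics and make
   thousands of matches implausible, so ±5% is read as ±0.05. Each control
   lead then receives as many LD partners as the trait region has members:
   first at r² > 0.9, unfilled slots retried at r² > 0.6, the rest left
   missing.

3. **Evaluation.** For a given measure, a control region is *marked* when
   fewer than 90% of the trait region's variants could be matched by a
   control member carrying a value; marked controls are excluded from the
   null. We deliberately count a slot as matched only when the member both
   exists and has a value, so structural shortfall and track missingness
   are handled by one rule. If ≥ 60% of a region's controls are marked the
   region is removed for that measure. Otherwise the observed statistic is
   the median of the measure over the region's variants, the null is the
   set of control-region medians, and the empirical p is the literal count
   rule p = #{control medians ≥ observed}/n (doubled smaller tail, capped
   at 1, for the bi-directional measures PhyloP, TMRCA and alignment block
   age). p = 0 is reported as the count rule produces it, with `n_used`
   recorded so users can floor at 1/n if they prefer. The z-score is
   (observed − mean)/sd of the control medians (sd with n−1). At least 100
   usable controls are required for a p-value; fewer yields an explicit
   missing value.

4. **Signatures and enrichment.** Z-scores form a region × measure matrix;
   measures missing in more than half the regions are dropped (as iHS
   typically is, its iHH ratios being undefined wherever either allele
   class is rare), remaining missing cells are imputed to 0 *for clustering
   geometry only* and masked so they never count as signatures. Rows are
   clustered (Euclidean distance, complete linkage) and the dendrogram cut
   at height 7; regions with at least one unimputed |z| ≥ 1.5 are the
   extreme-signature set. Set-level enrichment is tested two ways:
   genome-wide (count trait regions above the 95th percentile of 5000
   random-region medians, repeated 1000 times; the analytic null is
   Binomial with a 5% rate, e.g. 10.75 expected significant regions out of
   215) and matched (count trait regions with empirical p < 0.05, compared
   to the same count over 1000 random region sets evaluated against their
   own matched controls).

## The per-variant measures

* **Weir–Cockerham θ̂** (two populations): the a/(a+b+c) variance-component
  estimator from diploid sample sizes, alt-allele frequencies and observed
  heterozygote frequencies; overall-monomorphic sites are missing, not 0.
* **EHH family.** EHH at offset x from a core is the probability that two
  random carrier haplotypes are identical over all markers from the core to
  x; iHH integrates the curve by trapezoid on each side until the first
  point below 0.05. iHS is ln(iHH~anc~/iHH~der~) standardized within
  derived-frequency bins of width 0.025 (bins with fewer than 10 variants
  stay missing); ancestral alleles come from an explicit input map, never
  inferred. iES integrates the all-haplotype curve (EHHS); XP-EHH is
  ln(iES~A~/iES~B~) standardized over scored variants, positive when
  haplotype homozygosity is longer in A. Distances are physical bp (no
  genetic map); gap penalties used by some implementations are deliberately
  omitted.
* **Beta(1).** Nearby variants are weighted by folded-frequency similarity
  to the core, w = 1 − |f − f~c~|/0.5; β is the difference between the
  weight-based θ estimate (normalized by the neutral expectation of summed
  weight) and Watterson's θ on the same 1 kb window. Numeric equality with
  the original BetaScan binary is not claimed; the estimator is validated
  by its neutral mean-zero property and a direct-summation oracle.
* **Alignment block age**: the age (Myr) of the MRCA, on an ultrametric
  species tree, of the species present in the alignment block containing
  the focal species; a focal-only block has age 0.
* **Ingested tracks** (PhyloP, PhastCons, GERP, LINSIGHT, TMRCA) enter as
  (chrom, pos) → value tables and are indistinguishable from computed
  measures downstream; a YAML registry records each measure's tail
  convention (upper vs two-sided) and the |·| fold applied to iHS.

## Ancestral-state reconstruction

Per site, tip alleles over a species tree are reconstructed by unit-cost
Sankoff parsimony over the five states A, C, G, T and gap — gap is an
ordinary fifth state, with no affine treatment. Columns with more than one
gap are discarded before reconstruction as alignment-uncertain. Polytomies
are handled natively by the dynamic program rather than by arbitrary
resolution, which avoids hidden nondeterminism; the basal node of the input
tree is taken as the root. The reported per-node sets are full MPR sets
(every state attained by at least one minimum-change labeling), computed by
the standard up/down pass.

## The synthetic world

All tests and validation experiments run on data from a founder-mosaic
simulator (`simulatePanels()`): a small founder set, variants laid out in
founder-pattern blocks (consecutive variants carried by the same founder
subset, subset sizes weighted 1/k to skew folded frequencies low),
haplotypes copied founder-to-founder with per-bp recombination and
per-entry mutation, and population-specific Dirichlet founder weights
providing mild background differentiation (F~ST~ of a few percent, as
between human continental populations). This produces the block LD,
realistic MAF spectrum and buddy-count structure the matching machinery
needs, at a tiny fraction of a coalescent simulator's cost.

What it does **not** emulate: recombination hotspots, mutation-rate
heterogeneity, background selection, realistic site-frequency spectra at
the rare end, or genome-scale pool sizes. Passing tests therefore
demonstrate the *machinery* — matching logic, calibration of the empirical
p, recovery of planted effects — not population-genetic realism.

Planted signals give every stage a detectable target: `differentiated`
shifts a region's allele frequencies by δ in one population (toward the
side with room, so the between-population gap realises ~δ even at high
starting frequency); `sweep` copies one donor haplotype's segment into
carriers until it reaches a target frequency; `balanced` plants a
frequency-matched cluster at folded frequency 0.5; `conserved_track` adds
an offset to an ingested-style track over a region.

## Validation experiments and their design choices

`nullCalibration()` draws 200 trait-like regions from the same generator as
their controls and checks that the fraction with empirical p < 0.05 is near
0.05 per measure. `plantedRecovery()` plants 10 differentiated (δ = 0.6)
and 10 conserved-track (+3 sd) regions among 50 and checks that at least
8/10 of each class reach |z| ≥ 1.5 with the correct sign and p < 0.05,
while null regions are flagged at roughly the nominal rate. Both request
500 controls per region; as with real data, the attainable number varies
and is recorded.

Three design choices matter and were fixed a priori:

* **World size 24,000 variants over 24 chromosomes.** The empirical p is
  only as good as the diversity of its control medians. In small worlds the
  matched candidates for a lead concentrate in a handful of LD blocks, the
  control medians are mutually correlated, and z-scores overdisperse
  (sd ≈ 1.15 instead of 1). At 24k variants calibration is restored. The
  problem sizes keep both experiments under about a minute each.
* **Evaluable leads.** Experiment leads are restricted to common variants
  (folded MAF ≥ 0.10, as GWAS leads are) with at least 150 matched pool
  candidates. Recovery is assessed where the method reports; a region
  where the method abstains (fewer than 100 usable controls → missing p)
  is neither a success nor a failure of signal detection.
* **Trait-set exclusion.** No member of any evaluated trait region may
  serve as a control lead. In a genome-wide pool this leakage is
  negligible; in a desk-scale world the trait set is several percent of
  the pool, and planted signals would otherwise contaminate the nulls of
  other regions.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive everywhere after ingestion; BED and
  bedGraph are converted on read.
* Missing values propagate as explicit `NA`, never imputed at the data
  layer; a score-track lookup at an absent position is `NA`, not 0.
* Region medians ignore missing member values and require at least one
  non-missing value; even counts average the central pair.
* Monomorphic columns have undefined LD (an error for direct r² queries;
  treated as non-partners during clumping and matching).
* Integer matching windows are honest: a lead with 0 LD buddies accepts
  only candidates with exactly 0; ±10% of a count below 10 demands
  equality.
* All randomness flows from explicit integer seeds through one stream
  splitter; a pipeline rerun with the same configuration is byte-identical
  (verified by checksum in the tests).

## Known limitations

* F~ST~ is the two-population estimator; multi-population θ̂ is out of
  scope. Beta is the folded-spectrum β(1); the unfolded β(2) with
  substitution data is not implemented.
* The EHH family omits the gap-penalty and max-gap refinements of some
  implementations; iHS region summaries default to |iHS| (the registry
  makes this configurable), since region-level directionality of iHS is
  ambiguous.
* Which population anchors iES is an analysis choice; the pipeline computes
  it for the target population and labels outputs accordingly.
* The matched-enrichment null reuses the full matching machinery per
  iteration and is therefore the most expensive stage; fixture-scale runs
  lower `matched_n_iter` while the default remains 1000.
* LINSIGHT/GERP/PhyloP/PhastCons/TMRCA are ingested, never recomputed, and
  lifting coordinates between genome builds is out of scope.
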