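#' @import methods
NULL

## ---------------------------------------------------------------------------
## HaplotypePanel
## ---------------------------------------------------------------------------

#' Phased haplotype panel for one population
#'
#' Container for a phased, biallelic 0/1 haplotype matrix with one row per
#' haplotype (two per diploid sample) and one column per variant, plus the
#' variant coordinates. Columns are kept sorted by (chrom, pos); all
#' downstream LD, clumping and selection-scan machinery assumes this layout.
#'
#' @slot population Population label (e.g. `"EUR"`).
#' @slot variants `data.frame` with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`; one row per matrix column, in column order.
#' @slot haplotypes Integer matrix of 0/1 alleles, haplotypes x variants.
#'
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  slots = c(population = "character",
            variants = "data.frame",
            haplotypes = "matrix"))

setValidity("HaplotypePanel", function(object) {
  v <- object@variants
  h <- object@haplotypes
  msg <- character()
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(v)))
    return(paste("variants must have columns", paste(need, collapse = ", ")))
  if (ncol(h) != nrow(v))
    msg <- c(msg, "haplotype columns must match variant rows")
  if (nrow(h) %% 2L != 0L)
    msg <- c(msg, "haplotype row count must be even (two per diploid)")
  if (length(h) && !all(h %in% c(0L, 1L)))
    msg <- c(msg, "haplotype entries must be 0/1")
  if (anyDuplicated(v$id))
    msg <- c(msg, "variant ids must be unique within a panel")
  if (nrow(v)) {
    if (any(v$pos < 1L)) msg <- c(msg, "positions must be >= 1")
    if (any(v$ref == v$alt)) msg <- c(msg, "ref and alt must differ")
    o <- order(v$chrom, v$pos)
    if (!identical(o, seq_len(nrow(v))))
      msg <- c(msg, "variants must be sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' Sorts variants by (chrom, pos) and reorders the matrix columns to match.
#'
#' @param population Population label.
#' @param variants `data.frame` with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param haplotypes 0/1 matrix, haplotypes in rows, variants in columns.
#' @return A [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(population, variants, haplotypes) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  rownames(variants) <- NULL
  haplotypes <- haplotypes[, o, drop = FALSE]
  colnames(haplotypes) <- variants$id
  new("HaplotypePanel", population = population, variants = variants,
      haplotypes = haplotypes)
}

#' @rdname HaplotypePanel
#' @param object,x A `HaplotypePanel`.
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname HaplotypePanel
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)

#' @rdname HaplotypePanel
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname HaplotypePanel
#' @export
setMethod("variantInfo", "HaplotypePanel", function(x) x@variants)

#' @rdname HaplotypePanel
#' @export
setGeneric("panelPopulation", function(x) standardGeneric("panelPopulation"))
#' @rdname HaplotypePanel
#' @export
setMethod("panelPopulation", "HaplotypePanel", function(x) x@population)

#' @rdname HaplotypePanel
#' @export
nVariants <- function(x) ncol(x@haplotypes)

#' @rdname HaplotypePanel
#' @export
nHaplotypes <- function(x) nrow(x@haplotypes)

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel [", object@population, "]: ",
      nHaplotypes(object), " haplotypes x ", nVariants(object),
      " variants on ", length(unique(object@variants$chrom)),
      " chromosome(s)\n", sep = "")
})

## ---------------------------------------------------------------------------
## ScoreTrack
## ---------------------------------------------------------------------------

#' Per-variant values of one evolutionary measure
#'
#' A sparse (chrom, pos) -> value map for one measure, carrying the measure's
#' tail convention (`upper` for measures whose large values are the signal;
#' `two_sided` for bi-directional measures such as PhyloP, TMRCA and
#' alignment block age) and whether values were computed by this package or
#' ingested from an external source. Lookups at absent positions return `NA`,
#' never 0.
#'
#' @slot measureName Measure label.
#' @slot tail `"upper"` or `"two_sided"`.
#' @slot provenance `"computed"` or `"ingested"`.
#' @slot chrom,pos,value Parallel vectors of positions and values.
#' @slot keys Internal `chrom:pos` lookup keys.
#' @exportClass ScoreTrack
setClass("ScoreTrack",
  slots = c(measureName = "character", tail = "character",
            provenance = "character", chrom = "character",
            pos = "integer", value = "numeric", keys = "character"))

setValidity("ScoreTrack", function(object) {
  msg <- character()
  if (!object@tail %in% c("upper", "two_sided"))
    msg <- c(msg, "tail must be 'upper' or 'two_sided'")
  if (!object@provenance %in% c("computed", "ingested"))
    msg <- c(msg, "provenance must be 'computed' or 'ingested'")
  n <- length(object@pos)
  if (length(object@chrom) != n || length(object@value) != n ||
      length(object@keys) != n)
    msg <- c(msg, "chrom, pos, value, keys must have equal length")
  if (anyDuplicated(object@keys))
    msg <- c(msg, "duplicate positions in track")
  if (length(msg)) msg else TRUE
})

#' Construct a ScoreTrack
#'
#' Duplicate positions carrying identical values are collapsed; duplicates
#' with conflicting values are an error.
#'
#' @param measureName Measure label.
#' @param chrom,pos,value Parallel vectors.
#' @param tail `"upper"` or `"two_sided"`.
#' @param provenance `"computed"` or `"ingested"`.
#' @return A [ScoreTrack-class] object.
#' @export
ScoreTrack <- function(measureName, chrom, pos, value,
                       tail = c("upper", "two_sided"),
                       provenance = c("computed", "ingested")) {
  tail <- match.arg(tail)
  provenance <- match.arg(provenance)
  keys <- .key(chrom, pos)
  if (anyDuplicated(keys)) {
    agg <- tapply(value, keys, function(z) length(unique(z)))
    bad <- names(agg)[agg > 1L]
    if (length(bad))
      stop("duplicate position with conflicting values: ", bad[[1L]])
    keep <- !duplicated(keys)
    chrom <- chrom[keep]; pos <- pos[keep]; value <- value[keep]
    keys <- keys[keep]
  }
  new("ScoreTrack", measureName = measureName, tail = tail,
      provenance = provenance, chrom = as.character(chrom),
      pos = as.integer(pos), value = as.numeric(value), keys = keys)
}

#' Look up track values at positions
#'
#' @param track A [ScoreTrack-class].
#' @param chrom,pos Parallel position vectors.
#' @return Numeric vector with `NA` at positions absent from the track.
#' @export
trackLookup <- function(track, chrom, pos) {
  track@value[match(.key(chrom, pos), track@keys)]
}

#' @rdname ScoreTrack
#' @param x A `ScoreTrack`.
#' @export
measureName <- function(x) x@measureName

#' @rdname ScoreTrack
#' @export
trackTail <- function(x) x@tail

setMethod("show", "ScoreTrack", function(object) {
  cat("ScoreTrack '", object@measureName, "' (", object@tail, ", ",
      object@provenance, "): ", length(object@pos), " positions\n", sep = "")
})

## ---------------------------------------------------------------------------
## ControlSuite
## ---------------------------------------------------------------------------

#' Matched control regions for one trait region
#'
#' Holds the control regions assembled for a single trait-associated region:
#' for each control, the control lead plus partner slots filled at r^2 > 0.9,
#' refilled at r^2 > 0.6, or left missing. The structural match fraction per
#' control is (filled slots incl. lead) / trait region size.
#'
#' @slot regionId Trait region id (its lead variant id).
#' @slot regionSize Number of variants in the trait region (lead included).
#' @slot members `data.frame` with `control_index`, `member_id`,
#'   `matched_at` in `{"lead","0.9","0.6",NA}`; `regionSize` rows per control.
#' @slot nRequested Number of control regions requested.
#' @slot seed Seed used for all sampling in suite construction.
#' @exportClass ControlSuite
setClass("ControlSuite",
  slots = c(regionId = "character", regionSize = "integer",
            members = "data.frame", nRequested = "integer",
            seed = "integer"))

setValidity("ControlSuite", function(object) {
  m <- object@members
  msg <- character()
  if (!all(c("control_index", "member_id", "matched_at") %in% names(m)))
    return("members needs control_index, member_id, matched_at")
  if (nrow(m) && any(table(m$control_index) != object@regionSize))
    msg <- c(msg, "each control must have regionSize member slots")
  ok <- m$matched_at %in% c("lead", "0.9", "0.6") | is.na(m$matched_at)
  if (!all(ok)) msg <- c(msg, "matched_at must be lead/0.9/0.6/NA")
  if (length(msg)) msg else TRUE
})

#' @rdname ControlSuite
#' @param x A `ControlSuite`.
#' @export
nControls <- function(x) length(unique(x@members$control_index))

#' Structural match fraction per control region
#'
#' @param x A [ControlSuite-class].
#' @return Named numeric vector, one entry per control region: the fraction
#'   of trait-region slots (lead included) filled with a real variant.
#' @export
matchFraction <- function(x) {
  filled <- tapply(!is.na(x@members$member_id), x@members$control_index, sum)
  frac <- as.numeric(filled) / x@regionSize
  names(frac) <- names(filled)
  frac[order(as.integer(names(frac)))]
}

#' @rdname ControlSuite
#' @export
controlMembers <- function(x) x@members

setMethod("show", "ControlSuite", function(object) {
  mf <- matchFraction(object)
  cat("ControlSuite for region '", object@regionId, "': ",
      nControls(object), "/", object@nRequested,
      " controls of size ", object@regionSize,
      "; mean match fraction ", round(mean(mf), 3), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## NullDistribution
## ---------------------------------------------------------------------------

#' Matched-control null for one region x measure
#'
#' The medians of one evolutionary measure over the usable (unmarked) control
#' regions of a trait region. A control region is marked when fewer than 90%
#' of the trait region's variants could be matched with a control variant
#' carrying a value for this measure; marked controls are excluded from the
#' null. When at least 60% of controls are marked the region is removed for
#' this measure.
#'
#' @slot regionId,measureName Identifiers.
#' @slot controlMedians Medians of unmarked control regions.
#' @slot nMarked,nUsed Bookkeeping counts; `nUsed == length(controlMedians)`.
#' @slot removed `TRUE` iff marked fraction >= 0.60.
#' @exportClass NullDistribution
setClass("NullDistribution",
  slots = c(regionId = "character", measureName = "character",
            controlMedians = "numeric", nMarked = "integer",
            nUsed = "integer", removed = "logical"))

setValidity("NullDistribution", function(object) {
  if (object@nUsed != length(object@controlMedians))
    "nUsed must equal length(controlMedians)" else TRUE
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution ", object@regionId, " x ", object@measureName, ": ",
      object@nUsed, " used, ", object@nMarked, " marked",
      if (object@removed) " [REMOVED]", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## ZMatrix
## ---------------------------------------------------------------------------

#' Region x measure z-score matrix for clustering
#'
#' Rows are regions, columns measures. Measures missing in more than a set
#' fraction of regions are dropped on construction; remaining missing cells
#' are imputed to 0 for clustering geometry only, with the imputation mask
#' recorded so imputed cells never count as extreme signatures.
#'
#' @slot z Numeric matrix of z-scores (imputed where masked).
#' @slot mask Logical matrix, `TRUE` exactly where imputation occurred.
#' @slot droppedMeasures Measures removed for excess missingness.
#' @exportClass ZMatrix
setClass("ZMatrix",
  slots = c(z = "matrix", mask = "matrix", droppedMeasures = "character"))

setValidity("ZMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@z), dim(object@mask)))
    msg <- c(msg, "z and mask dimensions must agree")
  if (any(is.na(object@z)))
    msg <- c(msg, "z must be fully imputed")
  if (any(object@z[object@mask] != 0))
    msg <- c(msg, "masked cells must be imputed to 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ZMatrix", function(object) {
  cat("ZMatrix: ", nrow(object@z), " regions x ", ncol(object@z),
      " measures; ", sum(object@mask), " imputed cells",
      if (length(object@droppedMeasures))
        paste0("; dropped: ", paste(object@droppedMeasures, collapse = ", ")),
      "\n", sep = "")
})

#' @rdname ZMatrix
#' @param x A `ZMatrix`.
#' @export
zValues <- function(x) x@z

#' @rdname ZMatrix
#' @export
imputationMask <- function(x) x@mask
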