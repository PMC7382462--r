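## Readers and writers for the standard formats the pipeline touches:
## phased VCF + sample map, score tracks (TSV / bedGraph), GWAS summary
## statistics, gene BED, per-site tip-state tables, YAML measure registry.

#' Read a sample -> population map
#'
#' @param path TSV with header columns `sample_id`, `population`.
#' @return `data.frame` with those two columns.
#' @export
readSampleMap <- function(path) {
  sm <- .readTsv(path)
  if (!all(c("sample_id", "population") %in% names(sm)))
    stop("sample map needs columns sample_id, population")
  sm
}

#' Read a phased haplotype panel for one population from VCF
#'
#' Retains phased, biallelic SNP and indel records; multiallelic records are
#' skipped (with a logged count) and any variant column with a missing
#' genotype is dropped. The resulting matrix has two rows per diploid sample
#' of the requested population, in sample-map-free VCF column order, and one
#' column per retained variant after coordinate sorting.
#'
#' @param vcf_path Path to a VCF 4.x file with phased GT fields.
#' @param sample_map Path to a sample map TSV, or a `data.frame` with
#'   `sample_id` and `population` columns.
#' @param population Population label to extract.
#' @return A [HaplotypePanel-class].
#' @export
readHaplotypePanel <- function(vcf_path, sample_map, population) {
  if (is.character(sample_map)) sample_map <- readSampleMap(sample_map)
  samples <- sample_map$sample_id[sample_map$population == population]
  if (length(samples) == 0L)
    stop("population '", population, "' absent from sample map")

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_mat))) fix_mat <- t(fix_mat)  # single-record VCF
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no variants retained")

  biallelic <- !grepl(",", fix$ALT) & fix$ALT != "." & fix$REF != fix$ALT
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0L)
    message("readHaplotypePanel: skipped ", n_skipped,
            " non-biallelic record(s)")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  missing_samples <- setdiff(samples, colnames(gt))
  if (length(missing_samples))
    stop("samples absent from VCF: ", paste(missing_samples, collapse = ", "))
  gt <- gt[biallelic, samples, drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no variants retained")

  unphased <- grepl("/", gt)
  dim(unphased) <- dim(gt)  # grepl drops matrix dimensions
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1L, ]
    stop("unphased genotype at record ", fix$CHROM[bad[1L]], ":",
         fix$POS[bad[1L]], " sample ", samples[bad[2L]])
  }

  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  has_missing <- apply(a1 == "." | a2 == "." | is.na(gt), 1L, any)
  if (any(has_missing))
    message("readHaplotypePanel: dropped ", sum(has_missing),
            " variant(s) with missing genotypes")
  keep <- !has_missing
  fix <- fix[keep, , drop = FALSE]
  a1 <- a1[keep, , drop = FALSE]
  a2 <- a2[keep, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no variants retained")

  ## interleave the two haplotypes of each sample: rows 2i-1, 2i
  n_var <- nrow(fix)
  hap <- matrix(0L, nrow = 2L * length(samples), ncol = n_var)
  for (i in seq_along(samples)) {
    hap[2L * i - 1L, ] <- as.integer(a1[, i])
    hap[2L * i, ] <- as.integer(a2[, i])
  }
  id <- fix$ID
  noid <- is.na(id) | id == "."
  id[noid] <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")[noid]
  HaplotypePanel(
    population = population,
    variants = data.frame(id = id, chrom = fix$CHROM,
                          pos = as.integer(fix$POS), ref = fix$REF,
                          alt = fix$ALT, stringsAsFactors = FALSE),
    haplotypes = hap)
}

#' Write one or more panels (sharing variants) to a phased VCF
#'
#' @param panels A [HaplotypePanel-class] or list of panels over identical
#'   variants (e.g. one per population).
#' @param path Output VCF path.
#' @return Invisibly, a `data.frame` sample map for the written samples.
#' @export
writePanelVcf <- function(panels, path) {
  if (is(panels, "HaplotypePanel")) panels <- list(panels)
  v <- variantInfo(panels[[1L]])
  for (p in panels[-1L])
    if (!identical(variantInfo(p)$id, v$id))
      stop("all panels must share identical variants")

  sample_ids <- character()
  pops <- character()
  gt_cols <- list()
  for (p in panels) {
    h <- haplotypes(p)
    n_dip <- nrow(h) / 2L
    ids <- sprintf("%s_s%03d", panelPopulation(p), seq_len(n_dip))
    sample_ids <- c(sample_ids, ids)
    pops <- c(pops, rep(panelPopulation(p), n_dip))
    for (i in seq_len(n_dip))
      gt_cols[[length(gt_cols) + 1L]] <-
        paste(h[2L * i - 1L, ], h[2L * i, ], sep = "|")
  }
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                do.call(cbind, gt_cols))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  writeLines(c(header, apply(body, 1L, paste, collapse = "\t")), path)
  invisible(data.frame(sample_id = sample_ids, population = pops,
                       stringsAsFactors = FALSE))
}

#' Read a per-variant score track
#'
#' Accepts either a 3-column TSV (`chrom`, `pos`, `value`; 1-based positions,
#' optional header) or a 4-column bedGraph (0-based half-open intervals,
#' expanded to per-position 1-based values on read). Positions absent from
#' the input always look up as `NA`.
#'
#' @param path Input file.
#' @param measureName Measure label for the track.
#' @param tail Tail convention, `"upper"` or `"two_sided"`.
#' @param provenance `"ingested"` (default) or `"computed"`.
#' @return A [ScoreTrack-class].
#' @export
readScoreTrack <- function(path, measureName,
                           tail = c("upper", "two_sided"),
                           provenance = c("ingested", "computed")) {
  tail <- match.arg(tail)
  provenance <- match.arg(provenance)
  first <- strsplit(readLines(path, n = 1L), "[\t ]+")[[1L]]
  if (length(first) == 4L) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    chrom <- rep(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::width(gr))
    pos <- unlist(lapply(seq_along(gr), function(i)
      seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])))
    value <- rep(gr$score, GenomicRanges::width(gr))
  } else if (length(first) == 3L) {
    has_header <- is.na(suppressWarnings(as.numeric(first[2L])))
    df <- utils::read.table(path, header = has_header,
                            stringsAsFactors = FALSE)
    chrom <- as.character(df[[1L]])
    pos <- as.integer(df[[2L]])
    value <- as.numeric(df[[3L]])
  } else stop("score track must have 3 (TSV) or 4 (bedGraph) columns")
  ScoreTrack(measureName, chrom, pos, value, tail = tail,
             provenance = provenance)
}

#' Write a ScoreTrack as 3-column TSV
#'
#' @param track A [ScoreTrack-class].
#' @param path Output path.
#' @export
writeScoreTrack <- function(track, path) {
  .writeTsv(data.frame(chrom = track@chrom, pos = track@pos,
                       value = track@value), path)
}

#' Read GWAS summary statistics
#'
#' @param path TSV with header columns `variant_id`, `chrom`, `pos`, `p`.
#' @return `data.frame` with those columns; p values validated in (0, 1].
#' @export
readGwas <- function(path) {
  g <- .readTsv(path)
  need <- c("variant_id", "chrom", "pos", "p")
  if (!all(need %in% names(g)))
    stop("GWAS table needs columns ", paste(need, collapse = ", "))
  if (any(g$p <= 0 | g$p > 1)) stop("GWAS p values must be in (0, 1]")
  g
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; returned ranges are 1-based inclusive.
#'
#' @param path BED file.
#' @return A `GRanges` of gene intervals.
#' @export
readGeneBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) stop("empty gene set")
  gr
}

#' Read per-site tip-state table
#'
#' @param path TSV with header `site_id` then one column per species; states
#'   in `A`, `C`, `G`, `T`, `-`, or `NA` for species absent at that site.
#' @return Character matrix, sites x species, rownames = site ids.
#' @export
readTipStates <- function(path) {
  df <- .readTsv(path, na.strings = "NA")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$site_id
  m
}

## ---------------------------------------------------------------------------
## Measure registry
## ---------------------------------------------------------------------------

#' Default evolutionary-measure registry
#'
#' One row per measure with its tail convention and the transform applied to
#' per-variant values before region medians (`abs` folds signed iHS to |iHS|
#' for region-level summaries; all others pass through unchanged). Upper:
#' FST, |iHS|, XP-EHH, iES, Beta, PhastCons, GERP, LINSIGHT; two-sided:
#' PhyloP, TMRCA, alignment block age.
#'
#' @return `data.frame` with columns `measure`, `tail`, `transform`.
#' @export
defaultMeasureRegistry <- function() {
  data.frame(
    measure = c("fst", "ihs", "xpehh", "ies", "beta", "phastcons", "gerp",
                "linsight", "phylop", "tmrca", "block_age"),
    tail = c(rep("upper", 8L), rep("two_sided", 3L)),
    transform = c("identity", "abs", rep("identity", 9L)),
    stringsAsFactors = FALSE)
}

#' Read / write a measure registry as YAML
#'
#' @param path YAML file: a list of `measure`/`tail`/`transform` entries.
#' @return `data.frame` with columns `measure`, `tail`, `transform`.
#' @export
readMeasureRegistry <- function(path) {
  y <- yaml::read_yaml(path)
  reg <- do.call(rbind, lapply(y, function(e)
    data.frame(measure = e$measure, tail = e$tail,
               transform = if (is.null(e$transform)) "identity" else
                 e$transform,
               stringsAsFactors = FALSE)))
  if (!all(reg$tail %in% c("upper", "two_sided")))
    stop("registry tail must be upper/two_sided")
  if (!all(reg$transform %in% c("identity", "abs")))
    stop("registry transform must be identity/abs")
  reg
}

#' @rdname readMeasureRegistry
#' @param registry A registry `data.frame`.
#' @export
writeMeasureRegistry <- function(registry, path) {
  yaml::write_yaml(lapply(seq_len(nrow(registry)), function(i)
    as.list(registry[i, ])), path)
}

.applyTransform <- function(values, transform) {
  switch(transform, identity = values, abs = abs(values),
         stop("unknown transform: ", transform))
}
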