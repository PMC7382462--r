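## Small in-code fixtures shared across test files.

## panel from a plain 0/1 matrix; variants evenly spaced on one chromosome
## unless positions are given
makePanel <- function(mat, pos = NULL, chrom = NULL, population = "POP1") {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = n)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  HaplotypePanel(population,
                 data.frame(id = sprintf("s%03d", seq_len(n)),
                            chrom = chrom, pos = as.integer(pos),
                            ref = "A", alt = "G",
                            stringsAsFactors = FALSE),
                 mat)
}

## one-region table in the clumpRegions schema
makeRegion <- function(panel, lead_idx, member_idx = integer()) {
  v <- variantInfo(panel)
  idx <- c(lead_idx, member_idx)
  data.frame(region_id = v$id[lead_idx], member_id = v$id[idx],
             chrom = v$chrom[idx], pos = v$pos[idx], p = NA_real_,
             r2_to_lead = c(1, rep(NA_real_, length(member_idx))),
             is_lead = c(TRUE, rep(FALSE, length(member_idx))),
             stringsAsFactors = FALSE)
}

## hand-built control suite: control_values[[i]] gives the member values
## implied later by the paired track; member ids reference panel variants
makeSuite <- function(region_id, size, member_ids_per_control) {
  members <- do.call(rbind, lapply(seq_along(member_ids_per_control),
    function(ci) {
      ids <- member_ids_per_control[[ci]]
      n_missing <- size - length(ids)
      data.frame(control_index = ci,
                 member_id = c(ids, rep(NA_character_, n_missing)),
                 matched_at = c("lead", rep("0.9", length(ids) - 1L),
                                rep(NA_character_, n_missing)),
                 stringsAsFactors = FALSE)
    }))
  new("ControlSuite", regionId = region_id, regionSize = as.integer(size),
      members = members, nRequested = length(member_ids_per_control),
      seed = 1L)
}

## NullDistribution straight from a vector of control medians
makeNull <- function(control_medians, region_id = "r1", measure = "m",
                     n_marked = 0L, removed = FALSE) {
  new("NullDistribution", regionId = region_id, measureName = measure,
      controlMedians = as.numeric(control_medians),
      nMarked = as.integer(n_marked),
      nUsed = length(control_medians), removed = removed)
}

writeTempVcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

vcfHeader <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
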