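## one small fixture bundle + config shared by the pipeline tests
pipelineFixture <- function(seed = 59) {
  dir <- file.path(tempdir(), paste0("bundle_pipe_", seed))
  if (!dir.exists(dir)) {
    cfg <- simConfig(seed = seed, n_variants = 1200, n_chroms = 3,
                     n_diploids = 30,
                     planted_signals = list(
                       list(type = "differentiated", pop = "POP2",
                            region = 1, delta = 0.6)))
    suppressMessages(writeFixtureBundle(cfg, dir, n_regions = 6,
                                        n_genes = 40))
  }
  dir
}

pipelineConfig <- function(dir, seed = 7) {
  runConfig(
    vcf = file.path(dir, "panel.vcf"),
    sample_map = file.path(dir, "sample_map.tsv"),
    gwas = file.path(dir, "gwas.tsv"),
    genes = file.path(dir, "genes.bed"),
    tracks = c(phylop = file.path(dir, "tracks", "phylop.tsv"),
               gerp = file.path(dir, "tracks", "gerp.tsv")),
    target_pop = "POP1", comparison_pop = "POP2",
    measures = c("fst", "beta", "phylop", "gerp"),
    n_controls = 30L, min_controls = 10L,
    n_random = 300L, n_iter = 40L, matched_n_iter = 8L,
    seed = seed)
}
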