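Package: evoreg
Title: Evolutionary Signatures on Trait-Associated Genomic Regions via
    Matched Control Nulls
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies diverse evolutionary forces (negative selection,
    population differentiation, positive selection, balancing selection)
    acting on GWAS trait-associated genomic regions. Regions are built by
    greedy LD clumping of summary statistics, compared to minor-allele
    frequency, LD and gene-architecture matched control regions to obtain
    per-region empirical p-values and z-scores for each evolutionary
    measure, clustered by z signature, and tested for set-level enrichment
    against genome-wide and matched nulls. Includes per-variant estimators
    (Weir-Cockerham FST, EHH/iHH/iHS, XP-EHH, iES, Beta score, alignment
    block age), five-state parsimony ancestral reconstruction, and a
    founder-mosaic haplotype simulator for fully synthetic test fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    vcfR,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
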