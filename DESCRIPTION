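Package: chillmeth
Title: Windowed DMR Calling and Methylome-Transcriptome Integration for
    Chilling Accumulation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing DNA-methylation and transcriptome dynamics
    in dormant buds accumulating winter chill: parsing of per-cytosine
    bisulfite call reports, fixed-window log2-enrichment quantification and
    ANOVA-based calling of differentially methylated regions overall and per
    cytosine context (CpG/CHG/CHH), TMM normalisation and negative-binomial
    differential expression at FDR and fold-change thresholds, DMR-to-gene
    linking within a configurable flank, cross-genotype conservation of
    methylation/expression quadrants, methylation-expression correlation
    screens, hypergeometric term enrichment, and a fully seeded
    synthetic-experiment generator with planted truth tables so every stage
    is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    MASS,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
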