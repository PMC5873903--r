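Package: tnpool
Title: Combinatorially Pooled Arrayed Transposon Insertion Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Design and decoding of combinatorially pooled, arrayed
    transposon insertion libraries, and the downstream statistics used to
    interpret them. Constructs constant-weight binary pooling codes that
    assign each 96-well position to a subset of sequencing pools, converts
    pooled per-site read counts back into well assignments, maps insertions
    onto gene annotations, quantifies library saturation by rarefaction,
    predicts essential pathways by Monte-Carlo chi-square enrichment among
    genes with no insertions, and runs per-gene-family mixed-model
    association between gene presence/absence and host colonization load
    (log CFU) with Bonferroni control and pathway enrichment of top hits.
    Includes a synthetic-data generator with known ground truth for every
    pipeline input, and a config-driven end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
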