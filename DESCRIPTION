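Package: dupribo
Title: Translational Efficiency Divergence Between Duplicate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for translational regulation of plant
    duplicate genes from paired ribosome-profiling and mRNA-seq count
    data. Classifies paralogs into whole-genome, tandem and other
    duplicates versus singletons, computes FPKM-based translational
    efficiency and signed relative divergences per paralog pair, tests
    for translational buffering of transcriptional divergence (binomial
    and Wilcoxon signed-rank tests), estimates Ka/Ks by Nei-Gojobori
    counting with a Jukes-Cantor molecular-clock likelihood-ratio test
    for asymmetric sequence evolution, and detects differential
    translational efficiency across conditions with a negative-binomial
    GLM interaction test. Includes synthetic-data generators with known
    ground truth for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
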