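Package: mqtlseq
Title: Multiple QTL-Seq Mapping of Quantitative Trait Loci from Bulked
    Segregant Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bulk-based SNP-index and delta(SNP-index) QTL mapping for
    recombinant inbred line (RIL) populations, following the multiple
    QTL-seq strategy: per-SNP allele-frequency indices from bulk
    resequencing allele depths, sliding-window smoothing,
    simulation-based null confidence bands, QTL interval calling,
    cross-population consensus-interval narrowing, candidate SNP/gene
    delineation with structural variant annotation, and windowed
    nucleotide-diversity statistics (theta-pi, Tajima's D) for
    domestication scans. Includes a seeded synthetic-data generator
    emulating F9 RIL segregation, extreme-tail bulk constitution and
    Poisson/binomial read sampling so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
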