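Package: metabreadth
Title: Detection of Rare Bacterial Species in Shotgun Metagenomes by
    Coverage-Breadth Saturation
Version: 0.1.0
Authors@R:
    person("Metabreadth", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Competitive recruitment of metagenomic reads onto concatenated,
    rRNA-masked reference genomes at a species-level identity threshold,
    per-base coverage breadth and depth summaries, calibration of asymptotic
    breadth-saturation curves by stepwise read subsampling, and a calibrated
    presence/absence test for (possibly rare) bacterial species across many
    metagenomes. Also computes the overall genome-related indices used for
    prokaryotic species delimitation: fragment-based whole-genome average
    nucleotide identity (gANI) with alignment fractions, the 95 percent
    demarcation classifier, marker-gene (gyrB) identity typing, and genome
    summary statistics. A synthetic-community simulator (genomes, conspecific
    and related strains, error-bearing uniform reads) makes every stage
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    Rsamtools,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicAlignments,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
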