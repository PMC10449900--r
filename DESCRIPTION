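Package: dropmda
Title: Simulation and Analysis of Droplet-MDA Single-Cell Long-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse single-cell whole-genome
    amplification experiments that combine droplet multiple displacement
    amplification (dMDA) with long-read (HiFi-grade) sequencing. Includes a
    synthetic-data generator (diploid genomes with planted SNVs, structural
    variants, tandem repeats and a circular mitochondrial contig; clonal cell
    populations; droplet encapsulation; reagent-capped versus heavy-tailed
    amplification gain; amplification chimeras), a read self-alignment screen
    that detects and removes intramolecular chimeras (fold-back inversions and
    duplications), coverage-uniformity metrics (binned depth, extreme-coverage
    read fraction, breadth, coverage standard deviation, downsampling),
    truth-set evaluation of SNV and SV call sets with clone-aware somatic
    variant filtering and multi-sample SV merging, mitochondrial heteroplasmy
    detection from pileups, and confidence-filtered tandem-repeat genotyping
    from spanning long reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomicAlignments,
    data.table,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
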