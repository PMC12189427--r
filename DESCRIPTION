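Package: cytorec
Title: Broad-Scale Recombination Maps from Cytological Crossover Data
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts cytological crossover observations (MLH1 foci scored
    along pachytene synaptonemal complexes) into broad-scale recombination
    rate maps (cM/Mb) on fixed-size genomic interval grids, computes
    per-interval genomic feature tracks (GC content, CpG-island counts
    called from sequence by Gardiner-Garden-style criteria, gene density),
    and quantifies rank correlations between recombination rate and each
    feature per chromosome and pooled across chromosomes, with optional
    exclusion of zero-recombination intervals. Includes a synthetic-data
    generator for genomes with planted GC/CpG-island/gene structure and
    crossover datasets under homogeneous-terminal and polarized placement
    regimes, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    yaml,
    jsonlite,
    tools,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
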