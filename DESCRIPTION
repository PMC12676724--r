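Package: endotrawl
Title: Discovery and Temporal Analysis of Tiny Endosymbiont Genomes in Metagenomes
Version: 0.1.0
Authors@R:
    person("Endotrawl", "Developers", email = "endotrawl@example.org", role = c("aut", "cre"))
Description: A pipeline for trawling metagenomes for minute (234-375 kb)
    denitrifying endosymbiont genomes. Implements sequential marker-gene
    read prescreening with the BLAST Score Ratio (tlcA then nosZ) gated on
    marker coverage, reference-guided contig recruitment with a strict
    >3 kb rule, circularity detection by terminal repeat, a synteny audit
    that flags putative binning errors, single-copy marker completeness
    and contamination with MIMAG quality tiers, 16S identity-based species
    assignment, a breadth-of-coverage detection model
    (expected breadth = 1 - exp(-0.883 * depth)), and amplicon time-series
    analyses (relative abundance, detection fractions, seasonal windows,
    bloom calling). A synthetic-data generator produces genomes, reads,
    fragmented assemblies and multi-year count tables with known ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
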