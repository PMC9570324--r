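Package: methscan
Title: Bacterial SMRT Methylome Analysis and Methyltransferase Comparative Genomics
Version: 0.9.0
Authors@R:
    person("Methscan", "Developers", email = "methscan@example.org", role = c("aut", "cre"))
Description: Tools for analysing bacterial DNA methylomes derived from
    single-molecule real-time (SMRT) sequencing kinetics. Provides IUPAC
    motif scanning on linear and circular genomes, a simplified Welch-test
    kinetic modification caller with Phred-scaled modification QVs,
    per-motif methylation summaries, detection of unmethylated motif sites
    and Fisher exact tests for their enrichment in putative promoter
    regions, in-silico simulation of methylation-sensitive restriction
    enzyme (MSRE) PCR assays, presence/absence profiling of DNA
    methyltransferase repertoires with UPGMA and neighbor-joining trees,
    and a fully seeded synthetic-data generator so that every stage of the
    pipeline can be exercised offline with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
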