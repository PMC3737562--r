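Package: allele4C
Title: Allele-Specific 4C-seq Contact Profiling and Domain Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable implementation of
    allele-specific 4C-seq (circular chromosome conformation capture with
    sequencing) analysis. Builds in-silico double-digest fragment-end
    databases from diploid genomes, phases reads to parental alleles by a
    viewpoint SNP (paired-end strategy) or by a restriction-fragment-length
    polymorphism (single-end strategy), maps reads exactly to fragment-end
    prefixes, produces normalized running-median contact profiles with
    boundary detection, computes multi-scale binomial running-window
    significance maps (domainograms) with FDR-based interacting-domain
    calls, and quantifies cross-sample profile correlation and the
    transcriptional activity of contacted chromatin. A seeded synthetic-data
    module generates diploid genomes with SNPs and RFLPs, polymer-decay
    contact models with topological domains and enriched regions, FASTQ read
    sets with truth tables, and expression tracks, so every stage is
    verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
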