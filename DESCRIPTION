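Package: divscan
Title: Windowed Diversity, Selective-Sweep Scans and Regulatory Motif
    Enrichment for Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic scans of positive selection and
    cis-regulatory signal in small resequencing cohorts, modelled on the
    analysis of a solitary bee population (18 diploid females plus one
    haploid male). Implements a two-round VCF hard-filter cascade with a
    haploid-consistency check, windowed nucleotide diversity with a
    coverage-corrected denominator, windowed Tajima's D, per-individual
    heterozygosity and inbreeding, exact Hardy-Weinberg tests, Yang's
    unadjusted Ajk relatedness, a joint ECDF-percentile sweep scan over
    gene models, a two-state HMM partition-function motif scorer over
    sliding windows with rank and GC-binned rank normalization, gene-level
    Pgm motif scores over five regulatory-region definitions,
    conservative/liberal motif target sets, and one-sided Fisher exact
    enrichment with Benjamini-Hochberg correction. A synthetic-data module
    generates genomes, gene models, cohort variants with planted sweeps,
    coverage tracks and motif-planted promoters with truth tables so the
    whole pipeline is testable without any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
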