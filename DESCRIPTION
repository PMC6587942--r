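Package: hapblocks
Title: Haplotype-Block Inheritance and Selective-Sweep Analysis for Inbred
    Crop Pedigrees
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing biallelic SNP genotypes of near-homozygous
    (inbred or allohaploid) crop lines. Detects haplotype blocks with a
    Gabriel-style criterion based on one-sided confidence bounds on the
    normalised linkage-disequilibrium coefficient D-prime; scans for
    selective sweeps between trait groups using sliding-window nucleotide
    diversity, Fst and log diversity ratios; classifies blocks across a
    two-parent / focal-cultivar / progeny pedigree as family-shared,
    parent-inherited or recombined; maps candidate regions to genes; and
    simulates genotype panels with planted blocks, crossovers and sweep
    regions carrying full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    tools,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
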