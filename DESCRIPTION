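Package: lohscape
Title: Loss-of-Heterozygosity Detection from Population Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting loss of heterozygosity (LOH) genome-wide
    from pooled population sequencing. Computes per-site alternative allele
    frequencies from VCF files, detects homozygous tracts (runs of
    homozygosity) either as SNP-free blocks or as runs of fixed alternative
    alleles, compares parent and progeny populations site-by-site to find
    new LOH events, verifies collapsed homozygous alleles by coverage
    doubling against a diploid assembly, and evaluates Meselson-effect
    mutation-accumulation scenarios. Includes a synthetic-data generator
    that emulates diploid genomes with heterozygous SNPs, F1/F2 cross
    designs with meiotic crossovers, clonal (parthenogenetic) and selfing
    propagation, and sequencing noise, with full ground truth retained for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
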