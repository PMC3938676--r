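Package: gbstag
Title: Tag-Based SNP Discovery and Production Genotyping for
    Genotyping-by-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase analysis pipeline for reduced-representation
    genotyping-by-sequencing (GBS) assays. The Discovery phase collapses
    barcoded restriction-site-anchored reads into a master list of unique
    sequence tags, places tags with a unique best alignment on the physical
    map, tallies per-sample tag depths in a sparse tags-by-taxa matrix,
    discovers SNPs within multiple-aligned tag loci, calls genotypes with a
    binomial likelihood-ratio caller, and filters sites with
    population-genetic statistics (minor allele frequency, inbreeding
    coefficient F_IT, inbred coverage and inbred heterozygosity score). The
    Production phase genotypes new samples in a single step against the
    production-ready tag map and writes HapMap and VCF output. A seeded
    synthetic-data generator produces references, populations, and GBS FASTQ
    files with full truth tables, and a biparental-family error-rate
    estimator quantifies genotyping error from segregation distortion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
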