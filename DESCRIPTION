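Package: hetscan
Title: Heterozygosity-Aware Population Genomic Scans for Clonal and
    Outcrossing Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genetic analysis of diploid SNP genotype
    panels with an emphasis on variation in heterozygosity. Computes expected
    heterozygosity, nucleotide diversity, Tajima's D, Hudson and Nei FST,
    p-distance and linkage-disequilibrium decay from a genotype matrix;
    partitions a genome into heterozygous and homozygous regions from a
    reference accession and contrasts diversity between the two classes; calls
    per-accession heterozygous blocks and ranks their population frequency to
    define highly heterozygous (balancing-selection) blocks; scans for
    selective sweeps as windows in the empirical top percentile of
    wild-to-cultivar ratios of expected heterozygosity and nucleotide
    diversity; and tests heterozygous-versus-homozygous genotype classes
    against quantitative and categorical traits. A deterministic
    domestication-scenario cohort simulator with truth files supports
    end-to-end validation and recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
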