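Package: baftools
Title: Intensity-Based Allele Frequency Analysis for SNP Arrays
Version: 0.1.0
Authors@R: person("baftools", "maintainers", email = "baftools@example.org",
    role = c("aut", "cre"))
Description: Estimates coefficients of preferential amplification/hybridization
    (CPA) from heterozygous genotypes on two-channel SNP arrays, computes
    CPA-adjusted individual- and population-level allele frequencies (including
    DNA-pool allelotyping), detects allelic imbalance and loss of heterozygosity
    with a sliding-window scan against normal-control reference bands, classifies
    samples with rank-2 allele-frequency biplots, and estimates normal-cell
    contamination of tumor samples from allele frequencies of aberrant segments.
    Includes a seeded synthetic-data generator so every estimator is testable
    without array data, and a command-line interface wiring the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
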