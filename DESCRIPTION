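Package: sibtrace
Title: Ancient DNA Admixture Analysis: Pseudohaploid Genotyping,
    f-Statistics, qpAdm and Admixture-LD Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for the population-genetic analysis of
    low-coverage ancient genomes. Implements pseudohaploid genotype calling
    from sequence pileups, ancient-DNA authentication (coverage-based sex
    determination, terminal deamination profiling, and a supervised-ancestry
    contamination power analysis), f3/f4 statistics with weighted block
    jackknife errors, qpWave rank tests and qpAdm admixture-proportion
    estimation with a rotating-outgroup model search, weighted admixture-LD
    decay dating with calendar-date conversion, least-squares PCA projection
    of high-missingness samples, and radiocarbon calibration. A synthetic-data
    module generates allele frequencies under Balding-Nichols drift, admixed
    haplotypes with recombination, and damaged sequencing reads, so every
    stage of the pipeline can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
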