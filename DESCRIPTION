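Package: founderage
Title: Founder-Variant Carrier Frequencies, Autozygosity Mapping, and
    Mutation-Age Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native toolkit for founder-variant population
    studies: in-silico restriction-fragment-length-polymorphism (RFLP)
    genotyping, carrier-frequency estimation with exact (Clopper-Pearson)
    binomial confidence intervals and Hardy-Weinberg projection of recessive
    disease incidence, run-of-homozygosity (ROH) detection from per-marker
    genotype calls, physical-to-genetic map interpolation in sex-averaged
    Kosambi centimorgans, and dating of a founder mutation from the genetic
    lengths of carriers' shared autozygous segments. A forward simulator of
    founder-haplotype descent (exponential flank erosion, Hardy-Weinberg
    marker genotypes, binomial cohort sampling, and a deterministic RFLP
    amplicon fixture) makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
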