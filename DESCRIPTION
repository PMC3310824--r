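Package: crossphase
Title: Parental Genotype Inference and Linkage Phase Correction for
    Biparental Inbred Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers missing or incorrect parental genotypes of biparental
    inbred mapping populations (recombinant inbred lines and earlier selfing
    generations) from the segregation patterns of their progeny, infers the
    coupling/repulsion linkage phase of adjacent markers from a genetic map
    using Haldane's or Kosambi's map function, and automatically recodes
    ABH-coded genotype matrices to a consistent parental phase. Includes
    chi-square segregation tests for marker filtering, ACGT-to-ABH
    conversion, a seeded population simulator with ground truth for
    validation, readers and writers for tab-delimited genotype and map
    tables, a MapQTL .loc exporter, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
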