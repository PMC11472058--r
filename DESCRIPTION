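Package: capquant
Title: Quantitative Analytics for Chemically Modified mRNA Cap Analogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidyverse-native analysis toolkit for the biochemical
    characterization of trinucleotide mRNA cap analogs. Implements the
    ligand-depletion (quadratic) binding model for fluorescence quenching
    titrations against eIF4E, with dilution and inner-filter corrections,
    bounded multi-start nonlinear least-squares fitting and inverse-variance
    pooling of replicate association constants; spectrophotometric nucleotide
    quantitation from optical density; gel-lane densitometry with asymmetric
    least-squares baseline subtraction for capping-efficiency and decapping
    time-course statistics; normalization of reporter-protein luminescence
    time courses; and differential pull-down proteomics with an S0-moderated
    test and permutation-based FDR control. Includes seeded synthetic-data
    generators for every assay so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
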