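Package: mutbreedr
Title: Quantitative Genetics of Mutation-Breeding Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-generation mutagenesis field trials in
    self-pollinated crops. Simulates replicated randomized trials with known
    genotypic and plot-error variances, germination dose response and a linear
    path structure for yield; estimates variance components and the genetic
    parameters GCV, broad-sense heritability and genetic advance from one-way
    ANOVA mean squares; computes Duncan's multiple range test compact letter
    displays; Spearman correlation matrices and path-coefficient decomposition
    of yield into direct and indirect effects; population-level multivariate
    profiling (Euclidean distances, UPGMA dendrograms, correlation PCA with
    cos2 and contributions); truncation selection and realized genetic-gain
    accounting across generations; and spectrophotometric chlorophyll and
    carotenoid quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    yaml,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
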