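Package: ideofruit
Title: Gene-to-Phenotype Ideotype Design for Peach Fruit Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated gene-to-phenotype ideotype design for peach fruit
    quality. Couples a 31-locus additive QTL genetic model predicting seven
    parameters of a process-based fruit growth model (logistic dry-mass
    growth, stone allometry, sugar carbon balance) with a from-scratch
    NSGA-II multi-objective evolutionary optimizer over four nested search
    spaces: an observed parameter box, a genetically restricted box, the
    free 31-locus allele space, and a linkage-constrained allele space built
    from haplotype blocks. Includes a synthetic backcross progeny generator
    and the full estimation pipeline (nonlinear growth-curve fitting,
    allele-effect regression) so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
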