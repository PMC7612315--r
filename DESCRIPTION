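Package: cfdrv
Title: Conditional False Discovery Rates with Rigorous Type-1 Error Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariate-assisted multiple hypothesis testing via the conditional
    false discovery rate (cFDR). Pairs of p-values (a principal study and a
    conditional covariate study) are transformed into v-values that behave as
    p-values and can be passed to the Benjamini-Hochberg or Sidak procedures,
    using empirical-CDF rejection regions (L-regions) together with
    leave-one-out or block-out censoring so that each rejection map is
    independent of the observation it tests. Includes an
    expectation-maximisation fit of the mixture-Gaussian null for the
    covariate, oracle CDF/PDF comparators with exact mixture distributions, a
    simulation framework for FDR/power benchmarking, and an iterated procedure
    for conditioning on multiple covariate sets in succession.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
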