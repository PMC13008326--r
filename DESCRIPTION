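Package: angiotop
Title: Topological Summary Statistics, ABC-SMC Inference and Model Selection
    for Discrete Angiogenesis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tumour-induced angiogenesis with three discrete
    snail-trail models (Anderson-Chaplain lattice, Stokes-Lauffenburger
    off-lattice velocity, Plank-Sleeman discrete-angle), summarizes the
    resulting vascular networks with spatially-averaged statistics and
    extended persistent homology of sweeping-plane filtrations (vectorized
    as persistence images and persistence statistics), selects informative
    summary statistics with regression random forests, infers model
    parameters by ABC-SMC, and estimates model posteriors with a
    classification random forest paired with a regression random forest on
    its out-of-bag error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
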