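Package: phylodem
Title: Phylogenetic Signal in Demographic Traits of Tropical Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives genus-level life-history traits (potential size, growth
    and mortality rates, wood density) from repeated forest-census records,
    quantifies phylogenetic signal with Blomberg's K (with or without
    intrageneric measurement error), tip-randomization significance tests and
    Pagel's lambda, and performs phylogenetic principal component analysis.
    Includes a synthetic-data generator (pure-birth phylogenies, Brownian
    trait evolution, multi-census stem records) so that every stage of the
    pipeline can be validated against known truth without restricted
    plot-network data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
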