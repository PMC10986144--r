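Package: cueqs
Title: Cue-Based Quorum-Sensing Threshold Public-Goods Game Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-tier model family for the evolution of cue-based quorum
    sensing (QS) in microbial threshold public-goods games. Eight strategies
    built from three binary loci (cooperation C, extra signal S, signal
    response R) compete by pairwise cost-based imitation. The tiers are a
    deterministic mean-field approximation, an exact configuration-field
    model (multinomial enumeration of finite random interaction groups), a
    finite-population non-spatial agent-based simulation, and a spatially
    explicit toroidal lattice simulation with Moore-neighborhood groups and
    diffusive mixing. Tools are included for simplex vector fields,
    fixed-point inventories with stability classification, simulated drift
    fields, and steady-state genotype-distribution parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
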