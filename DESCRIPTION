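Package: decarc
Title: Dispersal-Extinction-Cladogenesis Models for Island-Arc Biogeography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood inference of geographic range evolution on
    dated phylogenies under the Dispersal-Extinction-Cladogenesis (DEC)
    family of models, including founder-event ("+J") cladogenesis and
    distance-dependent ("+x") dispersal, with time-stratified geographies
    (per-epoch distance, dispersal-multiplier and area-availability
    matrices).  Provides Felsenstein-pruning likelihoods over constrained
    range state spaces, multi-start model fitting, ancestral-range
    marginals, likelihood-ratio tests and AICc-based model comparison,
    an independent Fitch/Sankoff parsimony ancestral-area reconstruction
    with dispersal-event counting and per-area lineage-accumulation
    curves, and a forward (Gillespie) simulator of range histories on
    birth-death trees for validation and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    expm,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
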