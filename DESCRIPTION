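Package: chemquiz
Title: Algorithmically Generated Chemistry Questions with Verifiable Answers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates short-answer organic-chemistry questions with
    machine-verifiable ground truths across eight categories (atom and ring
    counting, shortest bond paths, atom mapping between SMILES
    representations, SMILES-to-IUPAC naming, Free-Wilson additive SAR
    analysis, reaction product prediction, and NMR structure elucidation
    from simulated 1D/2D spectra), and scores free-text answers with
    structure-aware equivalence rules. Includes a molecular graph engine
    with canonical, randomized and semicanonical SMILES writers, a
    rule-based NMR simulator, a restricted systematic-nomenclature parser,
    and benchmark evaluation statistics (binomial confidence intervals,
    one-tailed McNemar tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
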