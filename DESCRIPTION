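Package: telecycle
Title: Telegraph Gene Transcription Coupled to the Cell Division Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and stochastic tools for the two-state (telegraph)
    model of gene transcription coupled to a two-stage cell division cycle
    with gene duplication and binomial mRNA partitioning at division.
    Provides closed-form stationary means, second moments, noise and Fano
    statistics conditioned on cell-cycle stage, the S1-to-S2 fold change and
    its regime theory, time-dependent moment dynamics from a synchronized
    start, a truncated master-equation solver used as an independent oracle,
    an exact Gillespie lineage simulator, transcription- and
    concentration-homeostasis solvers under an exponential volume-growth
    model, and tidy parameter-scan utilities with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    deSolve,
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
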