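Package: thioreact
Title: Reactivity of Thiophene Photosensitizers Toward Singlet Oxygen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts how readily thiophene-containing photosensitizers are
    oxidised by singlet oxygen, a key photostability/safety trade-off in
    photodynamic therapy. Computes conceptual-DFT reactivity descriptors
    (vertical ionization potential and electron affinity, Mulliken
    electronegativity, hardness, global softness, electrophilicity, condensed
    Fukui functions and local softness) by finite differences over N, N-1 and
    N+1 electronic states; evaluates a fitted descriptor-based model for the
    log relative rate constant of singlet-oxygen cycloaddition, together with
    its experimental (methanol) calibration and an efficiency/safety
    classifier; provides Eyring transition-state-theory rate constants and
    log relative rates; and includes a from-scratch genetic-programming
    symbolic-regression engine for re-deriving descriptor-based rate models
    from tabulated data. Parsers for ORCA-style single-point output and
    deterministic synthetic-fixture generators are included so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
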