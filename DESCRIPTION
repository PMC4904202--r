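Package: ulvahydro
Title: Robust-Design Analysis of Thermochemical Hydrolysis of Ulva Biomass
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing thermochemical acid hydrolysis of green
    macroalgae (Ulva) as a biorefinery feedstock. Implements Taguchi
    "larger-the-better" signal-to-noise analysis of mixed-level orthogonal
    designs (per-level effect averages, sensitivity ranges, factor ranking
    and optimum settings), carbohydrate percent-yield statistics for
    hydrolysates, PLS1 regression of process outcomes on process factors
    with leave-one-out cross-validation, RPD diagnostics and Martens
    uncertainty variable selection, a resonating-micromembrane forward
    model and least-squares inversion for hydrolysate density, and flux
    balance / flux variability analysis of fermentation product yields
    from hydrolysate-derived media on tabular stoichiometric models.
    Includes generators for synthetic design-of-experiments tables, toy
    metabolic networks with known optima, and resonator observations.
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
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
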