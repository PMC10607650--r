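Package: lipidadapt
Title: Fatty Acid Profiling of Fungal Membrane Adaptation to CO2 and
    Temperature Stress
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of fatty acid methyl ester (FAME) composition
    profiles of yeasts and filamentous fungi under carbon dioxide and
    temperature stress. Parses fatty-acid shorthand nomenclature
    (chain length, double-bond positions and geometry, hydroxylation),
    computes the degree of unsaturation and the weighted average melting
    temperature (WAMT) of membrane fatty acids from replicate profiles
    with censored ("nd", "<1") cells, builds condition-contrast delta
    matrices with per-organism normalisation, performs Welch tests from
    replicate summary statistics, classifies membrane remodelling as
    fluidization or solidification, and simulates replicate compositional
    profiles with known condition effects for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
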