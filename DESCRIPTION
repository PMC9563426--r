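Package: somnospec
Title: Rodent Sleep EEG Staging, Band-Power Quantification and
    Architecture Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of rodent polysomnography: automated
    second-by-second wake/NREM/REM staging from spectrographic and
    accelerometer features, Welch band-power quantification with
    interquartile-range outlier exclusion and median normalization,
    sleep-architecture and fragmentation metrics, and a gated
    two-group statistical layer (independent t-test or Mann-Whitney,
    Bonferroni-corrected) for genotype comparisons. Includes a
    ground-truthed semi-Markov polysomnography simulator with
    configurable genotype effects on bout structure and band power,
    so the whole pipeline is testable without any recordings, plus
    minimal EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    car,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
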