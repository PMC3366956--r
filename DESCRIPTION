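Package: hippocode
Title: Hippocampal Electrophysiology Analysis: Ripples, Theta Phase and Place Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for in-vivo CA1 electrophysiology.
    Detects sharp wave/ripple events and theta oscillations in local field
    potentials, classifies tetrode-recorded units into pyramidal cells and
    interneurons by Mahalanobis distance to a pyramidal-cell template,
    quantifies place-cell spatial selectivity (rate maps, Skaggs information,
    sparsity, place-field detection in open field and linearized zigzag maze),
    and measures theta/ripple phase coding including theta phase precession by
    circular-linear correlation. A synthetic-session generator with recorded
    ground truth makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    signal,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
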