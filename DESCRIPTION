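Package: dichrosens
Title: Receptor-Noise Visual Models and Sensitivity Analysis of Avian
    Dichromatism Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying sexual dichromatism of plumage reflectance
    spectra through tetrachromatic receptor-noise visual models, and for
    assessing how sensitive those scores are to visual-system assumptions.
    Builds avian cone sensitivities from visual-pigment templates, oil-droplet
    cut-off filters and ocular-media transmission; computes von Kries-corrected
    quantum catches and chromatic contrasts in just-noticeable-difference (JND)
    units; scores and ranks species by mean male-female patch contrast; and
    drives single-parameter sweeps and exhaustive multi-parameter permutations
    over light environments, pigment peak sensitivities, oil-droplet and
    ocular-media properties, and photoreceptor density ratios. Includes a
    seeded synthetic plumage-spectra generator so the full pipeline is testable
    with known ground truth.
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
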