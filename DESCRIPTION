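Package: otolunar
Title: Otolith-Based Reconstruction of Lunar Birth Timing and
    Stage-Specific Selection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the lunar quarter of birth of reef
    fish from daily otolith increment records, and to quantify
    selection on birth timing across life-history stages. Includes a
    deterministic lunar-phase clock, a synthetic cohort simulator with
    moonlight-modulated larval growth and lunar-cued settlement,
    age-detrended residual-growth processing, extraction of twelve
    growth-history traits (trend/linearity/curvature, windowed slopes
    and intercepts, sinusoid amplitude and offset, pelagic larval
    duration), a linear discriminant birth-quarter classifier with
    leave-one-out cross-validation, and log10-ratio selection indices
    between successive life stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
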