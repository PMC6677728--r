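Package: mothvision
Title: Avian Visual Modelling of Larval Colour Change and Background Choice
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for quantifying insect colour change as
    perceived by an avian predator. Processes reflectance spectra onto a
    fixed 1 nm grid (300-700 nm), computes blue tit cone quantum catches
    under standard illuminants, derives greenness and luminance statistics,
    places stimuli in tetrahedral colour space, and evaluates chromatic and
    achromatic discriminability with the receptor-noise-limited (RNL) model
    in just-noticeable-difference (JND) units. Includes binomial GLMs for
    background-choice behaviour, RT-qPCR relative quantification with beta
    regression of dermal expression proportions, seeded synthetic-data
    generators for every stage, and an end-to-end orchestrated pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
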