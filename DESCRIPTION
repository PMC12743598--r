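Package: mrispr
Title: Tissue-Water Proton Stopping-Power Ratios from Proton-Density-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the tissue-water proton linear stopping-power ratio
    (SPR) from the hydrogen-concentration ratio measured by proton-density-
    weighted MRI. Provides reference tissue composition tables, first-order
    Bethe-Bloch stopping-power computation with Bragg-additivity mean
    excitation energies, linear calibration models linking hydrogen
    concentration to SPR (with dedicated lung and adipose-lipid routes), a
    GUM-style uncertainty budget (Type A/Type B composition, root sum square,
    Welch-Satterthwaite effective degrees of freedom), deuterium-oxide
    dilution phantom design, NEMA Method-4 signal-to-noise analysis of
    phantom images, and a seeded synthetic phantom generator with Rician
    noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
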