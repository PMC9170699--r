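Package: radnano
Title: Quantitative Analysis of Nanoparticle Radioenhancement Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of nanoparticle
    radioenhancement studies. Covers physicochemical conversions for
    nanoparticle materials (BET-equivalent diameters, mass/volume/surface-area
    concentration bases), analytic macroscopic dose-enhancement factors from
    spectrum-averaged mass energy-absorption coefficients, a seeded simplified
    photon Monte Carlo on vesicle and cell scoring geometries, quantification
    of chemical enhancement from acellular DCF fluorescence plates, the
    in-vitro survival pipeline (linear-quadratic fitting, dose-modifying
    ratios, sigmoid toxicity, DMSO radical-quenching decomposition), ICP-MS
    uptake saturation fitting with per-cell volume fractions, and seeded
    synthetic-data generators emulating the full experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
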