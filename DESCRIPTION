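Package: hdmea
Title: Spike-Train, Burst and Development Analysis for High-Density
    Multielectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of developing neuronal-network activity recorded on
    high-density CMOS multielectrode arrays (64x64 electrode grids).
    Provides differential-threshold extracellular spike detection,
    active-electrode filtering and mean-firing-rate statistics,
    single-electrode burst and network-burst detection,
    inter-burst-interval distributions, lognormal firing-rate
    distribution fitting and shift quantification, baseline-normalized
    homeostatic-plasticity classification, and estimation of the
    developmental GABA-polarity switch as the crossing point of NKCC1
    and KCC2 chloride-cotransporter expression time courses, with
    bootstrap confidence intervals. A seeded synthetic-data module
    generates ground-truth spike trains, raw voltage traces and
    expression curves so that every stage of the pipeline can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
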