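Package: catrisk
Title: Calcium-Transient Phenotyping and CiPA-Style Torsade Risk Classification
Version: 0.1.0
Authors@R: person("catrisk", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for drug-induced proarrhythmia analysis of spontaneously
    beating cardiomyocyte cultures recorded by calcium-sensitive fluorescence
    imaging. Detects calcium-transient (CaT) cycles in plate-based well
    time-series, computes a six-parameter waveform phenotype (P80, 8/2 ratio,
    cycle length, amplitude, peak number, cycle-length standard deviation),
    builds the three CiPA-style model predictors (arrhythmia waveform type,
    P80 at Cmax, maximum P80), and classifies compounds into high-,
    intermediate- and low-risk Torsade-de-Pointes categories with a
    ridge-penalized multinomial logistic model. Ships a seeded synthetic
    CaT generator emulating a control and an aged-phenotype (progeria)
    cardiomyocyte line with dose-dependent drug effects, so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
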