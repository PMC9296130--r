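Package: slimsep
Title: Separation Metrics and Simulation for SLIM Traveling-Wave Ion Mobility
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for characterizing high-resolution traveling-wave ion
    mobility separations on structures for lossless ion manipulation
    (SLIM) serpentine tracks. Provides deterministic instrument-geometry
    and waveform calculations, a seeded synthetic arrival-time trace
    generator built on a surfing/roll-over transport model with
    Mason-Schamp mobilities, Gaussian peak fitting, collision cross
    section (CCS) resolving power, two-peak resolution and percent-valley
    metrics, reduced-CCS calibration (power and polynomial models) with
    percent-bias assessment, and a desk-scale benchmarking pipeline over
    wave-speed/amplitude/waveform grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
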