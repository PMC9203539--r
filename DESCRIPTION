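Package: tympanr
Title: Smartphone Tympanometry: Simulation, Signal Processing and Clinical Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for 226 Hz probe-tone tympanometry performed with a
    low-cost pneumatic smartphone attachment. Implements the complete
    measurement pipeline: a physics-based simulator of the syringe-driven
    pressure sweep and admittance-dependent reflected tone, seal and
    occlusion detection from streaming pressure and audio, synchronization
    of the pressure and audio clocks from sweep-boundary notifications,
    single-bin FFT extraction of the probe-tone amplitude, cavity-based
    cubic calibration to millilitre equivalent volume, tympanogram
    smoothing, clinical metrics (peak admittance, peak pressure, ear canal
    volume), Liden-Jerger classification, and Bland-Altman device
    agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
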