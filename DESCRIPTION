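Package: cdmstrap
Title: Charge Detection Mass Spectrometry Simulation and Single-Ion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for charge detection mass spectrometry (CDMS) of
    megadalton particles such as adeno-associated virus (AAV) capsids.
    Simulates single-ion electrostatic-trap signals for configurable
    particle ensembles, recovers per-ion mass and charge by short-time
    Fourier transform harmonic fitting, and provides the downstream
    analyses used in CDMS studies of viral vectors: capsid stoichiometry
    mass accounting, Rayleigh-limit charge/diameter conversions,
    Gaussian-mixture decomposition of charge histograms, and
    classification of degradation and ligand-binding populations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
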