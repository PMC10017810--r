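Package: prowave
Title: Multi-Scale Diagnostics for Temperature-Light Species Distribution
    Models of Marine Picoplankton
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to probe temperature/light species distribution models of
    surface-ocean Prochlorococcus across spatial and temporal scales. Fits a
    two-state threshold niche model (zero abundance below a viability
    temperature, a fitted constant above it) and compares it against
    arbitrary parametric models in linear and log space. Provides Haar
    wavelet detection of sustained along-track abundance transitions,
    scale-dependent correlation between wavelet-filtered abundance and
    temperature, satellite-field colocalization with daily tolerance rules
    and depth-dependent light attenuation, monthly station fluctuation
    statistics with bootstrap uncertainties, and a seeded synthetic-data
    generator with ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
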