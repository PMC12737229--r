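Package: cwtburden
Title: Trajectory-Ensemble Source Attribution and Short-Term PM2.5 Health
    Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Receptor-oriented source attribution of fine particulate matter
    (PM2.5) from ensemble back-trajectories, and the associated short-term
    health burden. Reads and writes HYSPLIT-style trajectory endpoint files,
    grids trajectory residence on a regular latitude-longitude grid, computes
    the concentration-weighted trajectory (CWT) field with the standard
    sparse-cell weighting function, integrates the field over named source
    sectors, labels each day's dominant air-mass origin, and converts daily
    concentrations into relative risk and attributable fraction with
    sensitivity analysis over the concentration-response coefficient. A
    regime-switching trajectory and concentration simulator generates
    synthetic study scenarios so the whole pipeline is testable without
    external meteorological archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
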