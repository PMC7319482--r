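Package: synseasons
Title: Seasonal Picocyanobacteria Population Dynamics from Hourly Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates daily cell-division rates of Synechococcus-like
    picophytoplankton from hourly cell-size distributions using a
    size-structured matrix population model fit by maximum likelihood with a
    Dirichlet-multinomial observation model. Companion tools reconstruct the
    in-situ light environment (PAR attenuation coefficients from irradiance
    profiles, depth-averaged light exposure), build a stratification index
    from paired-depth temperature records calibrated against CTD density
    profiles, back-calculate population loss rates from net growth (dawn-to-
    dawn concentration change), reduce per-cell measurements to daily
    cell-property series, compute daily/weekly/monthly climatologies and
    anomalies, and fit saturating division-rate versus irradiance curves
    within temperature bins. A synthetic-data generator emulates every input
    so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    lhs,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
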