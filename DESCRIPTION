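Package: proxyshift
Title: Uncertainty-Aware Multi-Proxy Sediment-Core Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing paleoecosystem change from time-uncertain
    sediment-core proxy records. Computes derived proxy indices (fluxes,
    TOC-normalised biomarkers, sterol ratios, XRF count ratios, diatom
    assemblage indices), builds Monte Carlo age-depth ensembles from dated
    horizons, propagates measurement and dating uncertainty into per-proxy
    probability envelopes, synthesises records by principal component analysis
    with propagated uncertainty bounds, and detects intervals of significant
    change with penalized-spline trend models and first-derivative confidence
    intervals. Includes a synthetic-record generator with known truth for
    validation, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    nlme,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
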