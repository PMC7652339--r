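Package: tcellkin
Title: Kinetics of T-Cell Cytotoxicity and Proliferation from Live-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative live-cell imaging co-culture
    assays of engineered T cells. Converts per-well time series of live
    effector counts, dead-cell (red) pixel area and phase-contrast occupied
    area into fold proliferation, target death fraction, specific killing,
    per-T-cell killing and the corresponding proliferation and kill rates on
    a 6-hour grid, then fits four-parameter logistic dose-response curves to
    extract EC50 and Emax per receptor construct and effector:target ratio.
    Includes a stochastic co-culture simulator with ground truth, a synthetic
    three-channel frame renderer, and a transparent threshold-plus-
    connected-components segmentation so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
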