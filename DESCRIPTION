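Package: thermokin
Title: Model-Free Pyrolysis Kinetics from Multi-Heating-Rate Thermogravimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses non-isothermal thermogravimetric (TGA)
    experiments for single-step solid-state decomposition. Provides an
    Arrhenius curve simulator over the standard ICTAC reaction-model
    catalogue, conversion and DTG processing, activation-energy profiles by
    four model-free isoconversional methods (Kissinger-Akahira-Sunose,
    Flynn-Wall-Ozawa, Starink, Friedman), Kissinger peak-shift regression and
    frequency factors, transition-state activation thermodynamics
    (Gibbs energy, enthalpy, entropy), three-phase pyrolysis product-yield
    balances, and a small feed-forward neural-network surrogate for mass
    loss as a function of temperature and heating rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    nnet,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
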