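Package: bilayerTuring
Title: Turing Instability Analysis for Coupled Bilayer
    Reaction-Cross-Diffusion Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Linear stability and bifurcation analysis for two coupled
    layers of reaction-cross-diffusion equations in an epidermis/dermis-like
    geometry (a thin 1D surface exchanging species with a 1D or 2D bulk).
    Provides reaction-kinetics presets (Schnakenberg, pseudo-linear
    autocatalytic, linear Keller-Segel chemotaxis), dispersion relations
    with Routh-Hurwitz mode classification, critical bifurcation parameters
    as functions of the inter-layer coupling strength including weak- and
    strong-coupling asymptotic formulas, instability-region rasters, and a
    method-of-lines IMEX simulator for both geometries to verify the linear
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
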