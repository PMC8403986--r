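Package: dcstoich
Title: Stoichiometry Enumeration and Biophysical Analysis of the Beta-Catenin Destruction Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of reconstituted Wnt-pathway
    destruction complexes: per-slice SEC-MALS computations (concentration from
    differential refractive index, molar mass from light scattering, molar
    extinction coefficients via Beer-Lambert), peak summaries (weight- and
    number-average molar mass, dispersity), constraint-based enumeration of
    feasible integer complex stoichiometries from mass and extinction windows,
    Michaelis-Menten kinase kinetics with quadrature error propagation,
    mass-photometry contrast-to-mass calibration with fixed-bandwidth Gaussian
    kernel density estimates, and seeded synthetic-data generators with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    yaml,
    readr,
    generics,
    withr,
    minpack.lm,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
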