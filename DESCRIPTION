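Package: vlemix
Title: Vapor-Liquid Equilibria and Excess Properties of Binary Liquid Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for reducing isothermal total-pressure vapor-liquid
    equilibrium (P-x) measurements of binary liquid mixtures and for modeling
    their excess thermodynamic properties.  Implements Barker's method with the
    Wilson activity-coefficient model and a virial-corrected vapor phase,
    Antoine vapor-pressure regression, Redlich-Kister fitting of excess molar
    enthalpies and volumes, a Gibbs-Helmholtz consistency test linking excess
    Gibbs energy to calorimetric data, and three equations of state for
    correlation: Peng-Robinson-Mathias and Peng-Robinson-Stryjek-Vera cubics
    with Peneloux volume translation, and the Huang-Radosz formulation of the
    statistical associating fluid theory (SAFT).  Ships the complete
    (2-propanol + 1,8-cineole) study dataset as plain-text fixtures together
    with a synthetic-data generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
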