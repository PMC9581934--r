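Package: scco2sol
Title: Correlation of Solid Solute Solubility in Supercritical Carbon Dioxide
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlates isothermal solubility measurements of crystalline solids
    in supercritical carbon dioxide using density-based semi-empirical models
    (Chrastil, modified Chrastil, Mendez-Santiago-Teja, Bartle) and cubic
    equations of state (Redlich-Kwong, Peng-Robinson, and three- and
    four-parameter Soave-Redlich-Kwong) with Kwak-Mansoori
    temperature-independent mixing rules. Provides solute fugacity
    coefficients derived analytically and checked against the thermodynamic
    volume-integral definition, sublimation/solvation enthalpy estimation,
    crossover-pressure location, model-comparison statistics (AARD, R-squared,
    AIC/AICc), and a synthetic-data generator for parameter-recovery studies.
    Ships the crizotinib/scCO2 solubility table as a built-in validation
    dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
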