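Package: pegprecip
Title: Mechanistic Modeling of PEG-Induced Protein Precipitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a mechanistic precipitation isotherm for
    polyethylene-glycol (PEG) induced protein precipitation, in which the
    protein-protein complex is stabilized by bulk-like ordered water and the
    hydration number depends exponentially on PEG and initial protein
    concentration. Provides the implicit mass-action equilibrium solve with
    mass-balance closure, the classical Cohn semi-logarithmic baseline,
    laboratory unit conversions (mg/mL protein, % w/w PEG 6000), global
    parameter estimation by bounded simulated annealing with
    Levenberg-Marquardt polishing, the calibration/validation split used in
    high-throughput screen analysis, RMSEP computation, an in-silico 96-well
    precipitation-screen simulator with replicate noise and outlier
    pretreatment, CSV/JSON/YAML input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
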