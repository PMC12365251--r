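Package: pdnptrace
Title: Multi-Modal Quantification of Metal-Doped Nanoplastic Tracers in
    Biological Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification toolkit for palladium-doped
    polystyrene nanoplastic (Pd-NP) tracer studies. Provides a synthetic-data
    generator for first-order gastrointestinal transit of oral boluses with
    partial systemic uptake and for virtual instrument readouts; X-ray
    fluorescence imaging (XFI) quantification by Gaussian peak fitting and
    reference-target flux calibration with attenuation-bias bounds and
    detection limits; ICP-MS calibration with internal-standard drift
    correction and LOD/LOQ censoring; imaging mass cytometry (IMC) per-pixel
    dual-count statistics with titration-based sensitivity analysis; and
    dose-fraction mass-balance accounting (percent of daily dose, cumulative
    excretion, total recovery, group comparison, cross-method agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
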