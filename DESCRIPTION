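Package: voltmip
Title: Voltammetric Characterization and Validation of Molecularly
    Imprinted Polymer Sensors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for electrochemical sensors built on
    molecularly imprinted polymers (MIPs): peak extraction from cyclic and
    differential-pulse voltammograms with linear baseline correction;
    electron-transfer mechanism inference from pH and scan-rate series
    (Laviron transfer-coefficient product, half-peak-width transfer
    coefficient, electron count, diffusion/adsorption control
    classification); computational monomer screening by template-monomer
    binding-energy differences; analytical method validation (calibration
    with detection and quantitation limits, precision, spike recovery,
    interference percent change, reference-method comparison); and a
    seeded synthetic voltammogram generator with attached ground truth so
    the whole chain is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
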