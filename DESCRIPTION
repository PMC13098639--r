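Package: necrotherm
Title: Laser-Induced Liver Necrosis Prediction and Quantitative
    Immunohistochemistry Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts thermal necrosis in liver tissue exposed to pulsed
    near-infrared laser light and quantifies necrosis from digitized
    immunohistochemistry (IHC) sections. The prediction chain couples voxel
    Monte Carlo photon transport (Henyey-Greenstein scattering, implicit
    capture) to a finite-difference Pennes bioheat solver with blood
    perfusion and free-convection surface exchange, and integrates the
    Arrhenius thermal damage kinetics along the surface-probe temperature
    trace to obtain a necrotic-tissue percentage. The histology side plans
    power-of-two mosaics of whole-slide rasters, classifies
    hematoxylin-blue and DAB-brown cells by RGB box rules, scores 200-um
    patches with an exponential necrosis model, removes artifacts by
    two-stage Otsu/solidity filtering, and reconstructs necrosis volumes
    from rigidly registered serial sections. A synthetic-fixture module
    generates IHC-like sections, stacks and temperature traces with ground
    truth so the full pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    deSolve,
    EBImage,
    data.table,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
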