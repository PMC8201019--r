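Package: soilspec
Title: Soil Nutrient Estimation from VIS-NIR Imaging Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for estimating soil organic matter (SOM)
    and soil total nitrogen (STN) from visible/near-infrared reflectance
    spectra and hyperspectral image cubes. Provides scatter-correction
    preprocessing (multiplicative scatter correction, standard normal
    variate, spectral derivatives), sigma filtering of image cubes,
    wavelength selection by competitive adaptive reweighted sampling
    (CARS) coupled with the successive projections algorithm (SPA),
    partial least squares regression, extreme learning machine (ELM)
    regression with input weights optimized by particle swarm
    optimization (PSO-ELM), accuracy metrics (R2, RMSE, MAPE, RPD),
    stratified sample splitting, per-pixel inversion of nutrient maps
    from ENVI rasters, grade-area statistics, and a synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
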