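Package: moontrigger
Title: Nocturnal Sea-Surface Light Fields and the Lunar Trigger for Coral
    Broadcast Spawning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the wavelength-resolved light field at the sea surface
    (clear-sky solar, twilight, lunar, artificial light at night, and the
    dark-sky background), detects the extended period of minimum light
    intensity between sunset and moonrise that follows the full moon, and
    quantifies by how many nights coastal artificial light advances that
    period.  Also provides the companion statistical pipeline for coral
    spawning observations: classification of observations by underwater
    light-pollution exposure, construction of site covariates (raster buffer
    means, median-regression climate trends), a spatially autocorrelated
    Poisson mixed model with a Matern correlation structure, AIC-based
    selection over all nested models, likelihood-ratio tests, and per-genus
    lit-versus-unlit contrasts.  A synthetic-data generator reproduces the
    statistical structure the pipeline assumes so that every stage can be
    exercised end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmmTMB,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
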