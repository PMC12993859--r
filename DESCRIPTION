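Package: nutrimon
Title: Tiered Multispectral Nutrient Monitoring for Greenhouse Lettuce
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for tiered, energy-aware nutrient
    monitoring of greenhouse lettuce from overhead 10-channel multispectral
    imagery. Provides a synthetic depletion-experiment generator (logistic
    growth, tank-within-treatment random effects, reflectance links),
    vegetation-index feature extraction over per-plant masks, a lightweight
    autoencoder early-warning tier that flags anomalous growth trajectories by
    reconstruction error, random-forest state estimation of fresh weight, dry
    mass and six tissue nutrient concentrations under a leakage-free
    tank-permutation cross-validation scheme, a desk-scale multitask patch
    transformer alternative, and exact-arithmetic GPU-energy accounting with
    uncertainty propagation and embodied-nitrogen offset comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    png,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
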