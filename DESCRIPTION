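Package: dermvbe
Title: Mechanistic Dermal PBPK Modelling and Virtual Bioequivalence for Topical Formulations
Version: 0.1.0
Authors@R:
    person("Open", "Dermal PBPK Contributors", email = "dermvbe@example.org",
           role = c("aut", "cre"))
Description: A mechanistic pipeline for assessing the formulation safe space of
    topical (dermatological) drug products. Implements formulation
    characterisation and metamorphosis (volatile loss, tertiary composition,
    mixture density, vehicle diffusivity), a multilayer stratum-corneum /
    viable-epidermis / dermis permeation model with in vitro (Franz cell,
    IVPT) and in vivo boundary conditions, calibration of partition and
    corneocyte-permeability parameters to permeation data, in vitro-in vivo
    extrapolation to a minimal systemic model, virtual bioequivalence trial
    simulation with non-compartmental analysis and 90% confidence-interval
    assessment against the 80-125% limits, power analysis, and formulation /
    physiology / dose sensitivity sweeps. Includes a synthetic-data generator
    for replicate-level IVPT observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
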