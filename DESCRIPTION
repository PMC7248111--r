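Package: poolage
Title: Dating Human Blood Pools from the Drying Front
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Physics-based estimation of the time since deposition of a human
    blood pool from photographs of its drying front. Implements the pool
    drying model (shape factor, gravity-flattened contact angle, Knudsen
    layer, saturation vapour pressure, diffusion-weighted evaporation rate),
    the empirical mass versus wet-area relation, and a closed-form elapsed
    time estimator with Monte-Carlo uncertainty propagation. Includes drying
    curve analysis of mass and area time series, calibrated image
    segmentation of the wet and dried regions of a pool, and a seeded forward
    simulator and image renderer that reproduce the statistical structure of
    controlled drying experiments on non-porous surfaces.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'constants.R'
    'core_model.R'
    'drying_curves.R'
    'image_geometry.R'
    'age_estimator.R'
    'synthetic.R'
    'io.R'
    'cli.R'
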