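Package: MechanoKit
Title: Single-Molecule Pulling, Micropillar Traction and FRAP Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipelines for cellular mechanosensing studies of
    the talin rod R7-R8 region: simulation and analysis of single-molecule
    AFM force-extension experiments on polyproteins (worm-like-chain
    elasticity, Bell-Evans stochastic unfolding, contour-length-increment
    recovery, Gaussian histogram fits), micropillar traction-force
    microscopy (synthetic movie generation, subpixel spot localization,
    track linking, fiducial drift correction, displacement-to-force
    conversion), and FRAP recovery kinetics (normalization, exponential
    recovery fits with immobile fractions, extra-sum-of-squares F tests,
    stain-ratio quantification). Every stage is paired with a seeded
    synthetic-data generator so recovery accuracy is verifiable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'wlc.R'
    'construct.R'
    'pulling.R'
    'trace-analysis.R'
    'experiments.R'
    'frap.R'
    'io.R'
    'pillar.R'
    'pipeline.R'
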