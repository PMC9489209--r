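Package: chromobility
Title: Chromatin Locus Mobility from Live-Cell Single-Particle Tracking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the mobility of fluorescently tagged
    chromatin loci in 2D live-cell time-lapse microscopy. Detects and
    localizes single spots to sub-pixel precision, links them into
    trajectories with quality control, removes global stage drift,
    computes time-averaged mean squared displacement (MSD) curves over
    non-overlapping time intervals, fits the anomalous-diffusion power
    law MSD ~ D*t^alpha, and compares per-cell mobility between
    conditions with rank-based statistics, including a mixed-population
    resampling analysis. Ships a calibrated synthetic-data generator
    (confined fractional Brownian motion with measurement noise, drift
    and rendered image stacks) that provides ground truth for every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    parallel,
    stats,
    utils,
    tools,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: CellBiology, SingleCell, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chromobility-package.R'
    'drift.R'
    'fbm.R'
    'io.R'
    'methods-accessors.R'
    'msd.R'
    'pipeline.R'
    'render.R'
    'simulate.R'
    'stats.R'
    'tracking.R'
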