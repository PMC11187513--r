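Package: rhythmkit
Title: Dual-Modality Circadian Rest-Activity Rhythm and Sleep Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives sleep episodes and nonparametric circadian rhythm
    indicators (interdaily stability, intradaily variability, M10/L5,
    social jet lag) from two recording modalities: smartphone interaction
    logs aggregated into 5-minute "app-counts", and wrist actigraphy
    processed from raw tri-axial acceleration to per-minute activity
    counts with off-wrist exclusion and Cole-Kripke sleep scoring.
    Includes a paired synthetic-recording generator with known
    ground-truth circadian architecture for parameter-recovery testing,
    and noncentral-F power and balanced sample-size calculators for
    one-way ANOVA designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
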