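Package: placefieldr
Title: Place-Field Detection, Remapping and Position Decoding for Calcium
    Imaging on Virtual Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium imaging recorded while
    head-fixed mice run on circular virtual-reality tracks. Converts raw
    somatic and neuropil fluorescence plus deconvolved calcium events into
    occupancy-normalized lap-by-bin activity maps, detects place fields with a
    multi-step criterion, quantifies per-lap field dynamics (center-of-mass
    shift, field size, spatial information with a circular-shift null),
    measures global remapping through population-vector correlations and
    field-overlap statistics, decodes position with a leave-one-lap-out
    Bayesian decoder, scores anticipatory licking behavior, and fits lap-wise
    trends (linear and exponential-decay-with-offset). Includes a synthetic
    session generator with full ground truth so that every stage can be
    validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
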