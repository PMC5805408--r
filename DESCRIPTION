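Package: follipulse
Title: Quantification of Apical Pulses and Early Follicle Elongation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for quantifying apical pulsatile
    contractions and shape change in the early Drosophila ovarian follicle.
    Segments follicle cells on membrane-channel maximum projections with a
    marker-controlled watershed, tracks them by label overlap, and computes
    per-cell pulse intensity and isotropy, myosin-area cross-correlation
    lead-lag, follicle elongation coefficients with ANCOVA group comparison,
    per-pole extrapolated aspect ratios, spatial gradients of any per-cell
    metric against the distance from the polar cells, junctional
    planar-polarity angle profiles and the tissue cell-elongation tensor.
    Ships a synthetic-data generator (Voronoi epithelium with known pulse
    amplitudes, myosin lag, amplitude gradient and bond enrichment) against
    which every estimator is validated.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    minpack.lm,
    emmeans,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
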