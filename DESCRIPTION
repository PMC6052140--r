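Package: onoffscan
Title: Multi-Scale Center-Surround Analysis of ON/OFF Pathway Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the relative stimulation of retinal ON and OFF
    pathways in raster images and video frame sequences using a multi-scale
    center-surround receptive-field scan, with spatial-frequency calibration
    in cycles per degree. Includes deterministic generators for
    polarity-controlled text stimuli, luminance-matched pairs, checkerboards
    and 1/f-noise scene surrogates, and a statistics module for
    choroidal-thickness reading experiments: change-from-baseline summaries,
    paired t-tests, repeated-measures ANOVA, thinning-vs-refraction
    regression, and a synthetic cohort simulator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
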