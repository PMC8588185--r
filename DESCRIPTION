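Package: echoschool
Title: Echogram-Based Monitoring of Caged Fish School Responses to Underwater Noise
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the behavioral response of a caged fish school
    to acoustic stimuli from single-beam echosounder echograms. Provides a
    plain-text echogram container with stimulus event schedules, per-ping
    school envelope metrics (backscatter center of mass and upper/lower
    limits), fish-trace extraction via binarization, morphological cleaning
    and region segmentation with trace length and tilt indicators, calibrated
    hydrophone acoustics (SPL, peak level, third-octave and narrowband
    spectra, harmonic distortion), and a statistics layer (Levene test,
    unbalanced two-way ANOVA with Type III sums of squares, Tukey-Kramer
    homogeneous subsets, PCA composite response scoring). A synthetic
    cage/echosounder simulator with circadian depth rhythm, circular
    schooling and stimulus-triggered dive/contraction/speed/tilt reactions
    with habituation supplies ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
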