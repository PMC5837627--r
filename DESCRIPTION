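Package: therinf
Title: Simulation-Based Therapeutic Inference for Focal Brain Lesion Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the detectability of hypothetical therapeutic
    interventions in cohorts of patients with focal brain lesions. Binary lesion
    maps on a common analysis grid are manipulated (vectorization, volume,
    laterality, morphological surface erosion); a synthetic cohort generator
    produces stroke-like lesions with anatomy-dependent gaze deviation and
    recovery; a linear support vector machine relates the high-dimensional
    lesion pattern to recovery; and an iterated randomized-trial engine
    estimates, for lesion non-altering (responder-based) and lesion-altering
    (erosion-based) interventions, the empirical therapeutic function: the
    probability of detecting an intervention as a function of its effect size,
    with a monotone robust spline fit, threshold estimation and bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    pracma,
    withr,
    splines,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
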