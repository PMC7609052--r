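Package: plumewalk
Title: Stochastic Decision Models for Walking Olfactory Navigation in
    Intermittent Odor Plumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing and modelling how walking flies navigate
    spatiotemporally complex odor plumes. Provides a calibrated synthetic
    plume generator (advected odor packets under a telegraph cross-wind),
    virtual-antenna signal extraction and threshold-based encounter
    detection, exponentially filtered encounter statistics, trajectory
    smoothing and behavioral segmentation into walks, stops, and saccades,
    a stochastic saccade model with sigmoidal upwind bias, three competing
    inhomogeneous-Poisson rate models for walk/stop transitions with
    maximum-likelihood fitting and cross-validated comparison, orientation
    regression analyses, and an agent-based plume navigator with ablation
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    survival,
    yaml,
    jsonlite
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
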