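Package: taskstates
Title: Task EEG Microstate Segmentation, Simulation and Mixed-Design Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for event-related-potential (ERP) microstate analysis of
    task EEG: simulation of microstate-structured multichannel ERP cohorts with
    known ground truth and clinical-scale tables, ERP preprocessing (resampling,
    zero-phase band-pass filtering, epoching, baseline correction, artifact
    rejection, bad-channel interpolation, average referencing), polarity-invariant
    modified k-means segmentation of scalp topographies with global explained
    variance (GEV) and cross-validation (CV) model selection, backfitting and the
    four canonical microstate parameters (per-class GEV, mean duration, coverage,
    occurrence), and the mixed repeated-measures ANOVA designs (with covariates,
    Greenhouse-Geisser correction, simple effects and Holm adjustment) used to
    compare microstate parameters across clinical groups, emotional-cue
    conditions and treatment arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
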