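Package: csieval
Title: Dosimetric, Radiobiological and Deliverability Evaluation of
    Craniospinal Irradiation Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation toolkit for volumetric modulated arc therapy (VMAT)
    craniospinal irradiation (CSI) plans with functional-structure sparing.
    Computes exact (bin-free) cumulative dose-volume histograms and the
    standard dosimetric indices (D_x%, D_cc, V_xGy, homogeneity index,
    Paddick conformity index, vertebral dose gradient), four normal-tissue
    complication probability models (Lyman-Kutcher-Burman with gEUD or EQD2
    input, a multivariate parametric endocrine model, and a logistic
    cochlear model), a setup-uncertainty robustness index over a canonical
    30-scenario rigid perturbation set, eight MLC aperture complexity
    metrics for VMAT control-point sequences, and planned-versus-delivered
    QA comparison (global gamma analysis, DVH-metric deviations, and
    delivery-log RMS errors). A seeded synthetic head-and-spine phantom
    generator provides dose grids, structure masks, plans and delivery
    logs with controllable sparing dips and modulation, so the full
    pipeline runs end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
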