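Package: aerp
Title: Auditory Oddball ERP Analysis with Signed r-Squared Feature Selection
    and Single-Trial Name Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of auditory oddball event-related
    potential (ERP) experiments built around name stimuli: a synthetic
    session generator (pseudo-random no-repeat stimulus sequences,
    Gaussian-envelope ERP components in 1/f noise over a 60-channel 10-10
    montage), a preprocessing chain (linear-phase FIR band-pass, decimation,
    optional ICA-based ocular artifact removal, epoching, baseline
    correction, amplitude rejection), signed r-squared discriminability
    maps, correlation-constrained time-window feature selection, linear SVM
    target versus non-target classification with stratified cross-validation
    and repetition-aggregated name identification, ROC/AUC, and ERP
    amplitude/latency measurement with paired condition statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
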